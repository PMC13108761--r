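# broom-style tidiers ----------------------------------------------------------

#' @exportS3Method generics::tidy
tidy.gml_manifold <- function(x, ...) {
  matrix_to_tbl(x$embedding) |>
    stats::setNames(c("subject_id", paste0("dim", seq_len(x$d))))
}

#' @exportS3Method generics::glance
glance.gml_manifold <- function(x, ...) {
  tibble::tibble(n_reference = nrow(x$embedding),
                 n_features = ncol(x$reference_raw),
                 d = x$d, k = x$k,
                 prop_variance = sum(x$sdev[seq_len(x$d)]^2) / sum(x$sdev^2))
}

#' @exportS3Method generics::tidy
tidy.gml_deviations <- function(x, ...) {
  tidyr::pivot_longer(x$z, -"subject_id", names_to = "feature",
                      values_to = "z") |>
    dplyr::mutate(is_roi = .data$feature %in% x$roi_names,
                  abnormal = abs(.data$z) > x$threshold)
}

#' @exportS3Method generics::glance
glance.gml_deviations <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$z),
                 n_rois = length(x$roi_names),
                 threshold = x$threshold,
                 mean_bag = mean(x$summary$bag),
                 mean_n_abnormal = mean(x$summary$n_abnormal))
}

#' @exportS3Method generics::tidy
tidy.gml_risk_report <- function(x, ...) x$clusters

#' @exportS3Method generics::glance
glance.gml_risk_report <- function(x, ...) {
  tibble::tibble(k = nrow(x$clusters), n = sum(x$clusters$n),
                 rate_min = min(x$clusters$rate),
                 rate_max = max(x$clusters$rate),
                 fisher_min_p = min(x$fisher$p_value))
}

#' @exportS3Method generics::tidy
tidy.gml_trajectory <- function(x, ...) x$sampled

#' @exportS3Method generics::glance
glance.gml_trajectory <- function(x, ...) {
  tibble::tibble(roi = x$roi, n = x$n, crossing = x$crossing,
                 edf = sum(x$fit$edf), threshold = x$threshold)
}

#' @exportS3Method generics::tidy
tidy.gml_multinom <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.gml_multinom <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged,
                 separation = x$separation,
                 deviance = x$fit$deviance, aic = x$fit$AIC)
}
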