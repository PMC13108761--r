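# Plots ------------------------------------------------------------------------

#' @exportS3Method ggplot2::autoplot
autoplot.gml_deviations <- function(object, ...) {
  dat <- object$summary
  if (!"group" %in% names(dat)) abort_schema("no group labels to plot")
  dat$group <- factor(dat$group, group_levels())
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$bag,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "brain age gap (years)",
                  title = "Brain age gap across groups") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gml_risk_report <- function(object, ...) {
  if (is.null(object$coords)) abort_schema("report carries no 2-D coordinates")
  dat <- dplyr::left_join(object$coords, object$assignments, by = "subject_id") |>
    dplyr::left_join(object$clusters[c("cluster", "risk_label")],
                     by = "cluster")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                    colour = factor(.data$cluster),
                                    shape = .data$risk_label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "cluster", shape = "risk",
                  title = "RIS risk clusters in reduced deviation space") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gml_trajectory <- function(object, ...) {
  grid <- tibble::tibble(t = seq(0, 1, length.out = 200))
  grid$z <- as.numeric(predict(object$fit, newdata = grid))
  thr <- object$threshold
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$z)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = thr, ymax = 2.3,
                      fill = "yellow", alpha = 0.2) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 2.3, ymax = 3,
                      fill = "orange", alpha = 0.2) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 3, ymax = Inf,
                      fill = "red", alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$sampled,
                        ggplot2::aes(x = .data$pseudotime, y = .data$z)) +
    ggplot2::labs(x = "pseudotime", y = "fitted z",
                  title = sprintf("Trajectory: %s", object$roi)) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-ROI abnormality percentages by group
#'
#' @param map Output of [abnormality_map()].
#' @param top_n Show only the `top_n` ROIs with the highest overall burden.
#' @return A ggplot object.
#' @export
plot_abnormality_map <- function(map, top_n = 30) {
  keep <- map |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(m = mean(.data$pct_abnormal), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    dplyr::slice_head(n = top_n)
  dat <- map[map$roi %in% keep$roi, ]
  dat$group <- factor(dat$group, group_levels())
  dat$roi <- factor(dat$roi, rev(keep$roi))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$roi,
                                    fill = .data$pct_abnormal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% abnormal") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Regional abnormality burden (|z| > threshold)") +
    ggplot2::theme_minimal()
}
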