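# Shared fixtures, generated once per test run.

.fix <- new.env(parent = emptyenv())

small_config <- function(seed = 42, ...) {
  cohort_config(seed = seed, n_reference = 200, n_per_group = 40, ...)
}

# small generated cohort + features + fitted manifold + clinical deviations
get_small_pipeline <- function() {
  if (is.null(.fix$small)) {
    coh <- simulate_cohort(small_config())
    feat <- build_features(coh)
    ref <- subset_features_t(feat, feat$reference_ids)
    model <- fit_manifold(ref, coh$subjects)
    clin_ids <- coh$subjects$subject_id[coh$subjects$cohort == "matched"]
    dev <- score_subjects(model, subset_features_t(feat, clin_ids),
                          coh$subjects)
    .fix$small <- list(cohort = coh, features = feat, model = model,
                       deviations = dev)
  }
  .fix$small
}

subset_features_t <- function(features, ids) {
  out <- features
  out$values <- features$values[match(ids, features$values$subject_id), ]
  out
}

# Bare-bones feature object around a numeric matrix (identity scaling unless
# reference rows are named), for unit tests of the manifold operations.
toy_features <- function(m, reference_ids = rownames(m)) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  ref <- m[reference_ids, , drop = FALSE]
  scale <- apply(ref, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  structure(list(
    values = tibble::add_column(tibble::as_tibble(m),
                                subject_id = rownames(m), .before = 1),
    scaling = tibble::tibble(feature = colnames(m),
                             center = unname(colMeans(ref)),
                             scale = unname(scale)),
    roi_names = colnames(m), ai_names = character(),
    pairs = tibble::tibble(base = character(), left = character(),
                           right = character(), ai = character()),
    reference_ids = reference_ids
  ), class = "gml_features")
}

# deviations object wrapped around a given z matrix
toy_deviations <- function(z, threshold = 1.96) {
  structure(list(
    z = tibble::add_column(tibble::as_tibble(z),
                           subject_id = rownames(z), .before = 1),
    summary = tibble::tibble(
      subject_id = rownames(z),
      n_abnormal = as.integer(rowSums(abs(z) > threshold))),
    roi_names = colnames(z), threshold = threshold
  ), class = "gml_deviations")
}

expect_config_error <- function(expr) {
  expect_error(expr, class = "gmltwin_config_error")
}
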