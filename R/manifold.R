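# Manifold model and digital twins --------------------------------------------

#' Fit the healthy-reference manifold
#'
#' Learns a low-dimensional embedding of the standardized reference feature
#' space together with everything digital-twin scoring needs: reference
#' feature values, reference ages, and a precomputed leave-one-out (LOO)
#' twin residual for every reference subject. The LOO residual of reference
#' subject *j* is `actual_j - twin_j`, where `twin_j` is the mean feature
#' vector of *j*'s own `k` nearest reference neighbours excluding *j*; these
#' residuals later provide the local normal variability behind each patient's
#' GeoNorm z-scores.
#'
#' The embedding is principal component analysis of the standardized
#' reference features with component signs fixed (largest-magnitude loading
#' positive), which makes the fit fully deterministic, gives an exact linear
#' out-of-sample transform, and reproduces each reference row's coordinates
#' exactly. Dimension `d` and neighbour count `k` are tunable.
#'
#' @param features A `gml_features` holding the reference subjects.
#' @param ages Reference ages: a numeric vector aligned with the feature
#'   rows, or a subject tibble with `subject_id` and `age`.
#' @param d Embedding dimension (default 10).
#' @param k Neighbour count for twins (default 30; needs `k + 1 <=`
#'   reference size and `k >= 3` for the variability estimate).
#' @param sigma_floor Lower bound on the per-feature local SD, expressed in
#'   standardized units (default `1e-6`); prevents infinite z-scores in
#'   degenerate neighbourhoods.
#' @param seed Accepted for interface stability and threaded into the model
#'   manifest; the PCA embedding is deterministic regardless.
#' @return A `gml_manifold` model.
#' @export
fit_manifold <- function(features, ages, d = 10, k = 30,
                         sigma_floor = 1e-6, seed = NULL) {
  X <- standardize_features(features)
  n <- nrow(X)
  if (!is_count(k) || k < 3) abort_config("`k` must be an integer >= 3")
  if (k >= n) {
    abort_config(sprintf("`k` (%d) must be smaller than the reference size (%d)",
                         k, n))
  }
  ages <- resolve_ages(ages, rownames(X))

  d_eff <- min(d, ncol(X), n - 1)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = d_eff)
  rot <- fix_signs(pc$rotation)
  emb <- sweep(X, 2, pc$center, "-") %*% rot
  rownames(emb) <- rownames(X)

  raw <- tbl_to_matrix(features$values)[rownames(X), , drop = FALSE]

  # LOO twins for every reference subject
  D <- as.matrix(dist(emb))
  loo_resid <- matrix(NA_real_, n, ncol(raw), dimnames = dimnames(raw))
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    loo_resid[i, ] <- raw[i, ] - colMeans(raw[nb, , drop = FALSE])
  }

  structure(list(
    scaling = features$scaling,
    roi_names = features$roi_names,
    ai_names = features$ai_names,
    pc_center = pc$center,
    rotation = rot,
    embedding = emb,
    reference_ids = rownames(X),
    reference_raw = raw,
    reference_ages = ages,
    loo_resid = loo_resid,
    feature_scale = setNames(features$scaling$scale, features$scaling$feature),
    d = d_eff, k = k, sigma_floor = sigma_floor, seed = seed,
    sdev = pc$sdev
  ), class = "gml_manifold")
}

resolve_ages <- function(ages, ids) {
  if (is.data.frame(ages)) {
    ages <- setNames(ages$age, ages$subject_id)[ids]
  } else if (!is.null(names(ages))) {
    ages <- ages[ids]
  } else if (length(ages) != length(ids)) {
    abort_schema("`ages` length does not match the number of subjects")
  }
  ages <- as.numeric(ages)
  if (anyNA(ages)) abort_schema("missing age for one or more subjects")
  setNames(ages, ids)
}

fix_signs <- function(rotation) {
  flip <- apply(rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(rotation, 2, flip, "*")
}

#' Embed subjects into the fitted manifold
#'
#' Applies the frozen scaling and the model's linear transform to new feature
#' rows; applied to the reference itself it reproduces the stored embedding.
#'
#' @param model A `gml_manifold`.
#' @param features A `gml_features` (any subjects).
#' @return Tibble `subject_id` + `dim1..dimd`.
#' @export
embed_features <- function(model, features) {
  X <- standardize_query(model, features)
  E <- sweep(X, 2, model$pc_center, "-") %*% model$rotation
  colnames(E) <- paste0("dim", seq_len(ncol(E)))
  matrix_to_tbl(E)
}

standardize_query <- function(model, features) {
  m <- tbl_to_matrix(features$values)
  want <- model$scaling$feature
  if (!all(want %in% colnames(m)) || ncol(m) != length(want)) {
    abort_schema("feature columns do not match the fitted model")
  }
  m <- m[, want, drop = FALSE]
  sweep(sweep(m, 2, model$scaling$center, "-"), 2, model$scaling$scale, "/")
}

#' Find the k nearest reference neighbours of each subject
#'
#' Euclidean distances in embedding space; ties broken by reference index;
#' a query that is itself a reference subject never matches itself.
#'
#' @param model A `gml_manifold`.
#' @param features A `gml_features` holding the query subjects.
#' @param k Neighbour count; defaults to the model's `k`.
#' @return A tibble of class `gml_neighbors`: `subject_id`, `rank`,
#'   `neighbor_id`, `distance` (sorted ascending within subject).
#' @export
find_neighbors <- function(model, features, k = NULL) {
  k <- k %||% model$k
  n_ref <- nrow(model$embedding)
  if (!is_count(k) || k >= n_ref + 1) {
    abort_config("`k` must be a count below the reference size")
  }
  X <- standardize_query(model, features)
  Q <- sweep(X, 2, model$pc_center, "-") %*% model$rotation
  Rm <- model$embedding
  # squared cross distances, clamped at 0 against rounding
  d2 <- outer(rowSums(Q^2), rep(1, n_ref)) +
    outer(rep(1, nrow(Q)), rowSums(Rm^2)) - 2 * Q %*% t(Rm)
  d2[d2 < 0] <- 0
  ref_ids <- model$reference_ids
  out <- lapply(seq_len(nrow(Q)), function(i) {
    di <- sqrt(d2[i, ])
    self <- which(ref_ids == rownames(Q)[i])
    if (length(self)) di[self] <- Inf
    if (sum(is.finite(di)) < k) {
      abort_config("`k` must leave at least k non-self reference subjects")
    }
    ord <- order(di, seq_len(n_ref))[seq_len(k)]
    tibble::tibble(subject_id = rownames(Q)[i], rank = seq_len(k),
                   neighbor_id = ref_ids[ord], distance = di[ord])
  })
  structure(dplyr::bind_rows(out), class = c("gml_neighbors", class(tibble::tibble())))
}

#' Build digital twins from neighbour sets
#'
#' The twin of a subject is the unweighted mean feature vector (original
#' feature units) of its `k` reference neighbours; the local variability is
#' the per-feature SD of those neighbours' precomputed leave-one-out twin
#' residuals, floored at `sigma_floor` (standardized units).
#'
#' @param model A `gml_manifold`.
#' @param neighbors A `gml_neighbors` tibble from [find_neighbors()].
#' @return A list of class `gml_twin`: `twin` and `sigma` tibbles
#'   (subject x feature), each row one subject.
#' @export
build_twin <- function(model, neighbors) {
  ks <- table(neighbors$subject_id)
  if (any(ks < 3)) {
    abort_config("local variability needs at least 3 neighbours per subject")
  }
  raw <- model$reference_raw
  floor_vec <- model$sigma_floor * model$feature_scale[colnames(raw)]
  split_ids <- split(neighbors$neighbor_id, neighbors$subject_id)
  ids <- unique(neighbors$subject_id)
  twin <- matrix(NA_real_, length(ids), ncol(raw),
                 dimnames = list(ids, colnames(raw)))
  sigma <- twin
  for (s in ids) {
    nb <- match(split_ids[[s]], model$reference_ids)
    twin[s, ] <- colMeans(raw[nb, , drop = FALSE])
    res <- model$loo_resid[nb, , drop = FALSE]
    sigma[s, ] <- pmax(apply(res, 2, sd), floor_vec)
  }
  structure(list(twin = matrix_to_tbl(twin), sigma = matrix_to_tbl(sigma)),
            class = "gml_twin")
}

#' GeoNorm z-scores against a digital twin
#'
#' `z = (x - twin) / sigma_local` per feature; a region is flagged abnormal
#' when `|z|` exceeds the two-sided 5% threshold 1.96. Asymmetry-index
#' features are scored too but only ROI features count towards `n_abnormal`.
#'
#' @param features A `gml_features` with the scored subjects.
#' @param twin A `gml_twin` covering those subjects.
#' @param roi_names ROI feature names counted in `n_abnormal`.
#' @param threshold Two-sided abnormality threshold (default 1.96).
#' @return A list: `z` (tibble subject x feature) and `summary`
#'   (`subject_id`, `n_abnormal`).
#' @export
geonorm_z <- function(features, twin, roi_names = NULL, threshold = 1.96) {
  tm <- tbl_to_matrix(twin$twin)
  sm <- tbl_to_matrix(twin$sigma)
  xm <- tbl_to_matrix(features$values)[rownames(tm), colnames(tm), drop = FALSE]
  z <- (xm - tm) / sm
  roi_names <- roi_names %||% intersect(features$roi_names, colnames(z))
  n_abn <- rowSums(abs(z[, roi_names, drop = FALSE]) > threshold)
  list(z = matrix_to_tbl(z),
       summary = tibble::tibble(subject_id = rownames(z),
                                n_abnormal = as.integer(n_abn)))
}

#' Brain age and brain age gap from a neighbour set
#'
#' Brain age is the mean age of the subject's `k` nearest reference
#' neighbours; the brain age gap (BAG) is brain age minus chronological age.
#'
#' @param model A `gml_manifold`.
#' @param neighbors A `gml_neighbors` tibble.
#' @param chronological_age Named (by subject_id) or aligned numeric vector.
#' @return Tibble `subject_id`, `brain_age`, `bag`.
#' @export
brain_age <- function(model, neighbors, chronological_age) {
  ba <- neighbors |>
    dplyr::mutate(nb_age = model$reference_ages[.data$neighbor_id]) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(brain_age = mean(.data$nb_age), .groups = "drop")
  age <- resolve_ages(chronological_age, ba$subject_id)
  ba$bag <- ba$brain_age - unname(age)
  ba
}

#' Score subjects against the healthy manifold
#'
#' One call per cohort: embeds the subjects, finds their 30 nearest reference
#' neighbours, builds digital twins with leave-one-out local variability,
#' computes GeoNorm z-scores and the brain age gap.
#'
#' @param model A `gml_manifold`.
#' @param features A `gml_features` holding the subjects to score.
#' @param subjects Optional subject tibble (`subject_id`, `age`, and
#'   optionally `group`) used for BAG and carried into the summary.
#' @param threshold Abnormality threshold on |z| (default 1.96).
#' @return A list of class `gml_deviations`: `z` (subject x feature tibble),
#'   `summary` (`subject_id`, `group?`, `age?`, `brain_age`, `bag`,
#'   `n_abnormal`), `roi_names`, `threshold`.
#' @export
score_subjects <- function(model, features, subjects = NULL, threshold = 1.96) {
  nb <- find_neighbors(model, features)
  tw <- build_twin(model, nb)
  gz <- geonorm_z(features, tw,
                  roi_names = intersect(model$roi_names,
                                        names(features$values)),
                  threshold = threshold)
  summ <- gz$summary
  nb_age <- nb |>
    dplyr::mutate(nb_age = model$reference_ages[.data$neighbor_id]) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(brain_age = mean(.data$nb_age), .groups = "drop")
  summ <- dplyr::left_join(summ, nb_age, by = "subject_id")
  if (!is.null(subjects)) {
    keep <- intersect(c("subject_id", "group", "age", "converted",
                        "latent_subgroup"), names(subjects))
    summ <- dplyr::left_join(summ, subjects[keep], by = "subject_id")
    if ("age" %in% names(summ)) summ$bag <- summ$brain_age - summ$age
  }
  if (!"bag" %in% names(summ)) summ$bag <- NA_real_
  ord <- intersect(c("subject_id", "group", "age", "brain_age", "bag",
                     "n_abnormal", "converted", "latent_subgroup"),
                   names(summ))
  structure(list(z = gz$z, summary = summ[ord],
                 roi_names = intersect(model$roi_names, names(gz$z)),
                 threshold = threshold),
            class = "gml_deviations")
}

#' Save / load a fitted manifold model
#'
#' The archive restores a model whose downstream z-scores are bit-identical
#' to the original's.
#'
#' @param model A `gml_manifold`.
#' @param path File path (`.rds`).
#' @return `write_manifold()` returns `path` invisibly; `read_manifold()` the
#'   model.
#' @export
write_manifold <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_manifold
#' @export
read_manifold <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gml_manifold")) {
    abort_parse("file does not contain a gml_manifold model")
  }
  model
}

#' @export
print.gml_manifold <- function(x, ...) {
  cat("<gml_manifold>\n")
  cat(sprintf("  reference n=%d, features p=%d, embedding d=%d, k=%d\n",
              nrow(x$embedding), ncol(x$reference_raw), x$d, x$k))
  invisible(x)
}

#' @export
print.gml_deviations <- function(x, ...) {
  cat("<gml_deviations>\n")
  cat(sprintf("  %d subjects x %d scored features (%d ROIs), |z| > %.2f\n",
              nrow(x$z), ncol(x$z) - 1L, length(x$roi_names), x$threshold))
  invisible(x)
}
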