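# Feature construction ---------------------------------------------------------

#' Build the manifold feature space from raw ROI volumes
#'
#' Converts raw ROI volumes into the feature table the manifold consumes:
#' head-size-normalised volumes (volume / ICV) for every ROI plus one bounded
#' asymmetry index per Left/Right pair,
#' \deqn{AI = 2 (L - R) / (L + R) \in [-2, 2],}
#' computed on raw volumes (ICV cancels). Per-feature centring/scaling
#' parameters are learned on the reference subjects only and frozen before
#' any clinical subject is transformed.
#'
#' @param volumes ROI volume tibble (`subject_id` + one column per ROI), or a
#'   `gml_cohort`.
#' @param subjects Subject tibble with `subject_id` and `icv` (ignored when a
#'   `gml_cohort` is given).
#' @param reference_ids Ids of the subjects on which scaling is learned.
#'   Defaults to subjects with `cohort == "reference"`.
#' @return A list of class `gml_features`: `values` (tibble of raw feature
#'   values, ROI features then AI features), `scaling` (tibble
#'   feature/center/scale), `roi_names`, `ai_names`, `pairs`,
#'   `reference_ids`.
#' @export
build_features <- function(volumes, subjects = NULL, reference_ids = NULL) {
  if (inherits(volumes, "gml_cohort")) {
    subjects <- volumes$subjects
    volumes <- volumes$volumes
  }
  if (is.null(subjects) || !all(c("subject_id", "icv") %in% names(subjects))) {
    abort_schema("`subjects` must provide subject_id and icv")
  }
  vm <- tbl_to_matrix(volumes)
  roi_names <- colnames(vm)
  icv <- subjects$icv[match(rownames(vm), subjects$subject_id)]
  if (anyNA(icv)) abort_schema("every volume row needs a matching subject icv")

  pairs <- roi_pairs(roi_names)
  norm <- vm / icv
  ai <- NULL
  if (nrow(pairs)) {
    L <- vm[, pairs$left, drop = FALSE]
    R <- vm[, pairs$right, drop = FALSE]
    ai <- 2 * (L - R) / (L + R)
    colnames(ai) <- pairs$ai
  }
  values <- cbind(norm, ai)

  ref_ids <- reference_ids %||%
    subjects$subject_id[subjects$cohort %in% "reference"]
  if (!length(ref_ids)) {
    abort_schema("no reference subjects to learn feature scaling from")
  }
  ref <- values[rownames(values) %in% ref_ids, , drop = FALSE]
  center <- colMeans(ref)
  scale <- apply(ref, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1

  structure(list(
    values = matrix_to_tbl(values),
    scaling = tibble::tibble(feature = colnames(values),
                             center = unname(center), scale = unname(scale)),
    roi_names = roi_names,
    ai_names = if (is.null(ai)) character() else colnames(ai),
    pairs = pairs,
    reference_ids = rownames(ref)
  ), class = "gml_features")
}

# Resolve "Left X" / "Right X" pairs; an unpaired lateral name is a schema
# error (the asymmetry index would be undefined).
roi_pairs <- function(roi_names) {
  left <- roi_names[startsWith(roi_names, "Left ")]
  right <- roi_names[startsWith(roi_names, "Right ")]
  lbase <- sub("^Left ", "", left)
  rbase <- sub("^Right ", "", right)
  unpaired <- c(setdiff(lbase, rbase), setdiff(rbase, lbase))
  if (length(unpaired)) {
    abort_schema(paste0("unpaired lateral ROI name(s): ",
                        paste(unpaired, collapse = ", ")))
  }
  tibble::tibble(base = lbase,
                 left = left,
                 right = paste("Right", lbase),
                 ai = paste("AI", lbase))
}

# Standardised feature matrix (frozen reference scaling), optionally for a
# subset of subject ids.
standardize_features <- function(features, ids = NULL) {
  m <- tbl_to_matrix(features$values)
  if (!is.null(ids)) {
    missing <- setdiff(ids, rownames(m))
    if (length(missing)) abort_schema("unknown subject id(s) in `ids`")
    m <- m[ids, , drop = FALSE]
  }
  sc <- features$scaling
  sweep(sweep(m, 2, sc$center, "-"), 2, sc$scale, "/")
}

# Subset a gml_features object by subject id (scaling stays frozen).
subset_features <- function(features, ids) {
  out <- features
  keep <- match(ids, features$values$subject_id)
  if (anyNA(keep)) abort_schema("unknown subject id(s)")
  out$values <- features$values[keep, , drop = FALSE]
  out
}

#' Write / read a feature table
#'
#' `features.csv` mirrors the raw feature values; `feature_scaling.json`
#' serialises the frozen reference scaling so new subjects can be transformed
#' reproducibly.
#'
#' @param features A `gml_features`.
#' @param dir Directory.
#' @return `write_features()` returns `dir` invisibly; `read_features()` a
#'   `gml_features`.
#' @export
write_features <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(features$values, file.path(dir, "features.csv"), na = "")
  jsonlite::write_json(
    list(scaling = features$scaling, roi_names = features$roi_names,
         ai_names = features$ai_names, pairs = features$pairs,
         reference_ids = features$reference_ids),
    file.path(dir, "feature_scaling.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_features
#' @export
read_features <- function(dir) {
  values <- readr::read_csv(file.path(dir, "features.csv"),
                            show_col_types = FALSE, na = "")
  meta <- jsonlite::read_json(file.path(dir, "feature_scaling.json"),
                              simplifyVector = TRUE)
  structure(list(
    values = values,
    scaling = tibble::as_tibble(meta$scaling),
    roi_names = meta$roi_names,
    ai_names = meta$ai_names %||% character(),
    pairs = tibble::as_tibble(meta$pairs),
    reference_ids = meta$reference_ids
  ), class = "gml_features")
}
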