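# Cohort I/O -------------------------------------------------------------------
#
# subjects.csv: one row per subject, missing values as empty cells.
# volumes.csv:  subject_id + one named ROI column each, mm^3.
# cohort_config.json: the generating configuration, when known.

subject_col_types <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    cohort = readr::col_character(),
    group = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    latent_subgroup = readr::col_integer(),
    converted = readr::col_logical(),
    severity = readr::col_double(),
    icv = readr::col_double(),
    followup_years = readr::col_double(),
    spinal_cord_lesion = readr::col_character(),
    infratentorial_lesion = readr::col_character(),
    gadolinium_lesion = readr::col_character(),
    csf_positive = readr::col_character(),
    lesion_load = readr::col_double()
  )
}

#' Write / read a cohort directory
#'
#' `write_cohort()` writes `subjects.csv`, `volumes.csv` and (when the cohort
#' carries its generating configuration) `cohort_config.json` into `dir`.
#' `read_cohort()` reads them back; the round trip is an identity, including
#' column order and empty-cell missing-value encoding. Reading validates the
#' tables: duplicated subject ids, subject/volume row mismatches,
#' non-positive or non-finite volumes, and an ROI column count that
#' contradicts the stored configuration are all rejected with parse errors.
#'
#' @param cohort A `gml_cohort` (or a list with `subjects` and `volumes`).
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `gml_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"), na = "")
  readr::write_csv(cohort$volumes, file.path(dir, "volumes.csv"), na = "")
  if (!is.null(cohort$config)) {
    write_cohort_config(cohort$config, file.path(dir, "cohort_config.json"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  spath <- file.path(dir, "subjects.csv")
  vpath <- file.path(dir, "volumes.csv")
  if (!file.exists(spath) || !file.exists(vpath)) {
    abort_parse("cohort directory must contain subjects.csv and volumes.csv")
  }
  subjects <- readr::read_csv(spath, col_types = subject_col_types(), na = "")
  if (!"subject_id" %in% names(subjects)) {
    abort_parse("malformed subjects.csv header: no subject_id column")
  }
  vhead <- names(readr::read_csv(vpath, n_max = 0, show_col_types = FALSE))
  if (length(vhead) < 2 || vhead[1] != "subject_id") {
    abort_parse("malformed volumes.csv header: first column must be subject_id")
  }
  volumes <- readr::read_csv(
    vpath, na = "",
    col_types = do.call(readr::cols, c(
      list(subject_id = readr::col_character()),
      setNames(rep(list(readr::col_double()), length(vhead) - 1), vhead[-1])
    ))
  )
  if (anyDuplicated(subjects$subject_id)) {
    abort_parse("duplicated subject_id in subjects.csv")
  }
  if (!identical(volumes$subject_id, subjects$subject_id)) {
    abort_parse("volumes.csv subject ids do not match subjects.csv")
  }
  vm <- as.matrix(volumes[-1])
  if (anyNA(vm) || any(!is.finite(vm))) {
    abort_parse("volumes.csv contains missing or non-finite volumes")
  }
  if (any(vm <= 0)) abort_parse("volumes must be strictly positive")

  config <- NULL
  cpath <- file.path(dir, "cohort_config.json")
  if (file.exists(cpath)) {
    config <- read_cohort_config(cpath)
    if (ncol(volumes) - 1L != config$n_rois) {
      abort_parse(sprintf(
        "volumes.csv has %d ROI columns but the configuration declares %d",
        ncol(volumes) - 1L, config$n_rois))
    }
  }
  structure(list(subjects = subjects, volumes = volumes, config = config,
                 catalog = if (!is.null(config))
                   roi_catalog(config$n_rois, config$n_ris_subgroups)),
            class = "gml_cohort")
}
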