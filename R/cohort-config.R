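# Cohort configuration --------------------------------------------------------

#' Configuration for the synthetic morphometric cohort generator
#'
#' Defines the study conditions the generator emulates: a lifespan healthy
#' reference, three matched clinical groups (HC, RIS, MS) of equal size,
#' four latent RIS subgroups with planted five-year conversion risks spanning
#' 10-39%, a monotone structural severity gradient HC < RIS-NC < RIS-C < MS,
#' and a joint biomarker-availability gap among RIS subjects.
#'
#' @param seed Integer seed; identical seeds yield bit-identical cohorts.
#' @param n_reference Healthy reference size (manifold training set).
#' @param n_per_group Size of each matched clinical group (HC, RIS, MS).
#' @param n_rois Number of ROI volume columns (default 196, see
#'   [roi_catalog()]).
#' @param n_ris_subgroups Number of latent RIS subgroups.
#' @param subgroup_conversion_risks Five-year conversion probability per
#'   latent subgroup, each strictly inside (0, 1), ascending by convention.
#' @param severity_by_group Named mean disease severity per group
#'   (`HC`, `RIS-NC`, `RIS-C`, `MS`); must be non-decreasing in that order
#'   with `HC` the minimum. Severity 0 means no structural effect.
#' @param noise_sd Log-scale SD of the multiplicative volume noise.
#' @param female_fraction Female fraction of the clinical groups (exact count).
#' @param reference_female_fraction Female fraction of the reference.
#' @param age_range Two-element range (years) spanned by the reference.
#' @param clinical_age_mean,clinical_age_sd Age distribution of the clinical
#'   groups (normal, truncated to `age_range`).
#' @param biomarker_availability Fraction of RIS subjects with the joint
#'   biomarker panel available (spinal cord, infratentorial, gadolinium, CSF
#'   are jointly missing for the rest); realised as an exact count.
#' @param subgroup_effect Multiplier on the subgroup-specific cortical block
#'   atrophy; 1 is the well-separated regime, 0 removes subgroup geometry.
#' @param subgroup_block_beta Log-volume atrophy per unit severity applied to
#'   each subgroup's reserved ROI block.
#' @param late_stage_exponent Exponent applied to severity for late-stage
#'   (diffuse cortical) regions: their atrophy accrues as
#'   `severity^late_stage_exponent`, so diffuse involvement is
#'   disproportionately an established-disease feature (default 1.5).
#' @param subgroup_vent_scale Per-subgroup multiplier on the ventricular
#'   disease effect (graded onset: higher-risk subgroups enlarge earlier);
#'   default `seq(0.4, 1.2, length.out = n_ris_subgroups)` (MS itself has
#'   scale 1).
#' @param severity_jitter SD of the per-subject log-normal severity
#'   multiplier (within-group heterogeneity; drives pseudo-time spread).
#' @param cord_lesion_probs Per-subgroup probability of a spinal-cord lesion
#'   (the planted cluster-associated biomarker). Default for four subgroups:
#'   `c(0.20, 0.45, 0.45, 0.20)`.
#' @param biomarker_probs Named probabilities for the remaining biomarkers
#'   (`infratentorial`, `gadolinium`, `csf`), constant across subgroups.
#' @param site_offset_sd Optional per-site multiplicative log offset SD
#'   (0 disables site effects).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_reference = 1000,
                          n_per_group = 152,
                          n_rois = 196,
                          n_ris_subgroups = 4,
                          subgroup_conversion_risks = c(0.10, 0.15, 0.25, 0.39),
                          severity_by_group = c("HC" = 0, "RIS-NC" = 0.35,
                                                "RIS-C" = 0.55, "MS" = 1.1),
                          noise_sd = 0.05,
                          female_fraction = 0.77,
                          reference_female_fraction = 0.53,
                          age_range = c(18, 85),
                          clinical_age_mean = 41.2,
                          clinical_age_sd = 13.8,
                          biomarker_availability = 94 / 152,
                          subgroup_effect = 1,
                          subgroup_block_beta = 0.4,
                          late_stage_exponent = 1.5,
                          subgroup_vent_scale = NULL,
                          severity_jitter = 0.2,
                          cord_lesion_probs = NULL,
                          biomarker_probs = c(infratentorial = 20 / 94,
                                              gadolinium = 11 / 94,
                                              csf = 68 / 94),
                          site_offset_sd = 0) {
  cfg <- list(
    seed = as.integer(seed),
    n_reference = n_reference, n_per_group = n_per_group, n_rois = n_rois,
    n_ris_subgroups = n_ris_subgroups,
    subgroup_conversion_risks = subgroup_conversion_risks,
    severity_by_group = severity_by_group, noise_sd = noise_sd,
    female_fraction = female_fraction,
    reference_female_fraction = reference_female_fraction,
    age_range = age_range, clinical_age_mean = clinical_age_mean,
    clinical_age_sd = clinical_age_sd,
    biomarker_availability = biomarker_availability,
    subgroup_effect = subgroup_effect,
    subgroup_block_beta = subgroup_block_beta,
    late_stage_exponent = late_stage_exponent,
    subgroup_vent_scale = subgroup_vent_scale %||%
      seq(0.4, 1.2, length.out = n_ris_subgroups),
    severity_jitter = severity_jitter,
    cord_lesion_probs = cord_lesion_probs %||%
      (if (n_ris_subgroups == 4) c(0.20, 0.45, 0.45, 0.20)
       else rep(31 / 94, n_ris_subgroups)),
    biomarker_probs = biomarker_probs,
    site_offset_sd = site_offset_sd
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (fld in c("n_reference", "n_per_group", "n_rois", "n_ris_subgroups")) {
    if (!is_count(cfg[[fld]])) {
      abort_config(sprintf("`%s` must be a positive integer count", fld))
    }
  }
  if (cfg$n_rois > 196) abort_config("`n_rois` cannot exceed 196")
  risks <- cfg$subgroup_conversion_risks
  if (length(risks) != cfg$n_ris_subgroups) {
    abort_config("`subgroup_conversion_risks` must have one entry per subgroup")
  }
  if (any(!is.finite(risks)) || any(risks <= 0) || any(risks >= 1)) {
    abort_config("conversion risks must lie strictly within (0, 1)")
  }
  sev <- cfg$severity_by_group
  if (!all(group_levels() %in% names(sev))) {
    abort_config("`severity_by_group` must name HC, RIS-NC, RIS-C and MS")
  }
  sev <- sev[group_levels()]
  if (any(diff(sev) < 0) || sev[["HC"]] > min(sev)) {
    abort_config("severity ordering violated: need HC <= RIS-NC <= RIS-C <= MS")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    abort_config("`noise_sd` must be non-negative")
  }
  for (fld in c("female_fraction", "reference_female_fraction",
                "biomarker_availability")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort_config(sprintf("`%s` must be a probability in [0, 1]", fld))
    }
  }
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0) {
    abort_config("`age_range` must be an increasing length-2 range")
  }
  if (length(cfg$subgroup_vent_scale) != cfg$n_ris_subgroups ||
      any(cfg$subgroup_vent_scale <= 0)) {
    abort_config("`subgroup_vent_scale` must be positive, one per subgroup")
  }
  if (length(cfg$cord_lesion_probs) != cfg$n_ris_subgroups ||
      any(cfg$cord_lesion_probs < 0 | cfg$cord_lesion_probs > 1)) {
    abort_config("`cord_lesion_probs` must be probabilities, one per subgroup")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  seed %d | reference n=%d | clinical groups n=%d x 3 | %d ROIs\n",
              x$seed, x$n_reference, x$n_per_group, x$n_rois))
  cat(sprintf("  RIS subgroups: %d, conversion risks %s\n", x$n_ris_subgroups,
              paste(format(x$subgroup_conversion_risks), collapse = ", ")))
  cat(sprintf("  severities: %s\n",
              paste(sprintf("%s=%.2f", group_levels(),
                            x$severity_by_group[group_levels()]),
                    collapse = " ")))
  invisible(x)
}

#' Read or write a cohort configuration file
#'
#' Configurations round-trip losslessly through JSON or YAML.
#'
#' @param config A `cohort_config`.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a validated `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  # named vectors must serialise as maps, not bare arrays
  x$severity_by_group <- as.list(x$severity_by_group)
  x$biomarker_probs <- as.list(x$biomarker_probs)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 17) # doubles must round-trip
  } else {
    abort_parse("config path must end in .json, .yaml or .yml")
  }
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    abort_parse("config path must end in .json, .yaml or .yml")
  }
  x$severity_by_group <- unlist(x$severity_by_group)
  x$biomarker_probs <- unlist(x$biomarker_probs)
  do.call(cohort_config, x)
}
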