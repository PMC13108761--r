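# Synthetic cohort generator --------------------------------------------------

#' Simulate a morphometric study cohort
#'
#' Generates a seeded synthetic cohort: a lifespan healthy reference, matched
#' HC / RIS / MS clinical groups, latent RIS subgroups with planted conversion
#' risks, and per-subject ROI volumes built from the deterministic product
#'
#' \deqn{V_{sr} = \mathrm{baseline}_r \times \mathrm{icv\_scale}_s \times
#'   \mathrm{age}_r(a_s) \times \mathrm{sex}_r(s) \times
#'   \mathrm{disease}_r(s) \times e^{\varepsilon_{sr}},\quad
#'   \varepsilon_{sr} \sim N(0, \sigma^2)}
#'
#' where the disease factor enlarges ventricular regions and shrinks
#' parenchymal regions in proportion to the subject's latent severity, each
#' latent RIS subgroup additionally atrophies its own reserved cortical ROI
#' block (geometric separability), and the ventricular effect is scaled per
#' subgroup (graded onset). RIS subjects draw `converted` from a Bernoulli
#' with their subgroup's planted risk; the `RIS-C` / `RIS-NC` labels follow
#' from that draw.
#'
#' @param config A [cohort_config()].
#' @return A list of class `gml_cohort` with elements `subjects` (one row per
#'   subject: demographics, group, latent truth, biomarkers, outcome),
#'   `volumes` (`subject_id` + one strictly positive mm^3 column per ROI),
#'   `config`, and `catalog` (the [roi_catalog()] used).
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 1, n_reference = 60,
#'                                      n_per_group = 12))
#' dplyr::count(coh$subjects, cohort, group)
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  cat <- roi_catalog(config$n_rois, config$n_ris_subgroups)
  blocks <- attr(cat, "subgroup_blocks")
  with_seed(config$seed, {
    subjects <- simulate_subjects(config)
    volumes <- simulate_volumes(subjects, cat, blocks, config)
    structure(list(subjects = subjects, volumes = volumes,
                   config = config, catalog = cat),
              class = "gml_cohort")
  })
}

simulate_subjects <- function(cfg) {
  nr <- cfg$n_reference
  np <- cfg$n_per_group
  sev <- cfg$severity_by_group

  draw_clin_age <- function(n) {
    a <- rnorm(n, cfg$clinical_age_mean, cfg$clinical_age_sd)
    pmin(pmax(a, cfg$age_range[1]), cfg$age_range[2])
  }

  ref <- tibble::tibble(
    subject_id = sprintf("HCref%04d", seq_len(nr)),
    cohort = "reference", group = "HC",
    age = runif(nr, cfg$age_range[1], cfg$age_range[2]),
    sex = ifelse(exact_bernoulli(nr, cfg$reference_female_fraction), "F", "M")
  )
  hc <- tibble::tibble(
    subject_id = sprintf("HC%04d", seq_len(np)),
    cohort = "matched", group = "HC",
    age = draw_clin_age(np),
    sex = ifelse(exact_bernoulli(np, cfg$female_fraction), "F", "M")
  )
  ris <- tibble::tibble(
    subject_id = sprintf("RIS%04d", seq_len(np)),
    cohort = "matched", group = NA_character_,
    age = draw_clin_age(np),
    sex = ifelse(exact_bernoulli(np, cfg$female_fraction), "F", "M")
  )
  ms <- tibble::tibble(
    subject_id = sprintf("MS%04d", seq_len(np)),
    cohort = "matched", group = "MS",
    age = draw_clin_age(np),
    sex = ifelse(exact_bernoulli(np, cfg$female_fraction), "F", "M")
  )
  subjects <- dplyr::bind_rows(ref, hc, ris, ms)
  n <- nrow(subjects)
  is_ris <- startsWith(subjects$subject_id, "RIS")

  # latent subgroups: balanced counts, random order
  sg <- rep(NA_integer_, n)
  sg[is_ris] <- sample(rep_len(seq_len(cfg$n_ris_subgroups), np))
  subjects$latent_subgroup <- sg

  conv <- rep(NA, n)
  conv[is_ris] <- rbinom(np, 1, cfg$subgroup_conversion_risks[sg[is_ris]]) == 1
  subjects$converted <- conv
  subjects$group[is_ris] <- ifelse(conv[is_ris], "RIS-C", "RIS-NC")

  subjects$severity <- sev[subjects$group]
  jit <- exp(rnorm(n, 0, cfg$severity_jitter))
  subjects$severity <- unname(subjects$severity * jit)

  subjects$icv <- exp(log(1.45e6) + 0.10 * (subjects$sex == "M") +
                        rnorm(n, 0, 0.07))

  subjects$followup_years <- ifelse(
    is_ris, pmax(0.1, rnorm(n, 3.3, 3.5)), NA_real_)

  # biomarker panel: jointly available for an exact fraction of RIS subjects
  avail <- rep(FALSE, n)
  avail[is_ris] <- exact_bernoulli(np, cfg$biomarker_availability)
  yn <- function(p_vec) ifelse(avail, ifelse(rbinom(n, 1, p_vec) == 1,
                                             "yes", "no"), NA_character_)
  cord_p <- rep(0, n)
  cord_p[is_ris] <- cfg$cord_lesion_probs[sg[is_ris]]
  subjects$spinal_cord_lesion <- yn(cord_p)
  subjects$infratentorial_lesion <- yn(cfg$biomarker_probs[["infratentorial"]])
  subjects$gadolinium_lesion <- yn(cfg$biomarker_probs[["gadolinium"]])
  subjects$csf_positive <- yn(cfg$biomarker_probs[["csf"]])

  subjects$lesion_load <- ifelse(
    subjects$group == "HC", 0L, rpois(n, 4 + 6 * subjects$severity))
  subjects
}

simulate_volumes <- function(subjects, cat, blocks, cfg) {
  n <- nrow(subjects)
  R <- nrow(cat)
  age_ref <- 45

  log_v <- matrix(rep(log(cat$baseline), each = n), n, R)
  log_v <- log_v + log(subjects$icv / 1.45e6)
  log_v <- log_v + outer(subjects$age - age_ref, cat$age_slope)
  log_v <- log_v + outer(as.numeric(subjects$sex == "M"), cat$sex_log)

  # disease: signed per-ROI delta, linear in severity for early-involved
  # structures, severity^gamma for late diffuse cortical atrophy;
  # ventricular effect scaled per latent RIS subgroup (graded onset)
  vent_scale <- rep(1, n)
  is_ris <- !is.na(subjects$latent_subgroup)
  vent_scale[is_ris] <- cfg$subgroup_vent_scale[subjects$latent_subgroup[is_ris]]
  gamma <- cfg$late_stage_exponent
  sev_stage <- cbind(early = subjects$severity, late = subjects$severity^gamma)
  sev_eff <- sev_stage[, cat$stage, drop = FALSE] *
    matrix(rep(cat$disease_delta, each = n), n, R)
  vent_cols <- cat$tissue %in% c("ventricle", "csf")
  sev_eff[, vent_cols] <- sev_eff[, vent_cols] * vent_scale
  log_v <- log_v + sev_eff

  # Subgroup signature: a trait-like atrophy pattern in the rank-2 block
  # plane, fixed at RIS onset (scaled by the configured RIS-NC mean severity,
  # not by the subject's own progressing severity).
  if (cfg$subgroup_effect > 0 && any(is_ris)) {
    sets <- attr(cat, "block_sets")
    coeffs <- attr(cat, "block_coeffs")
    amp <- cfg$subgroup_effect * cfg$subgroup_block_beta *
      cfg$severity_by_group[["RIS-NC"]]
    for (g in seq_len(cfg$n_ris_subgroups)) {
      rows <- which(is_ris & subjects$latent_subgroup == g)
      if (!length(rows)) next
      for (ax in c("A", "B")) {
        cols <- match(sets[[ax]], cat$roi)
        cols <- cols[!is.na(cols)]
        cf <- coeffs[g, match(ax, c("A", "B"))]
        if (length(cols) && cf > 0) {
          log_v[rows, cols] <- log_v[rows, cols] - amp * cf
        }
      }
    }
  }

  if (cfg$noise_sd > 0) {
    log_v <- log_v + matrix(rnorm(n * R, 0, cfg$noise_sd), n, R)
  }
  vol <- exp(log_v)
  colnames(vol) <- cat$roi
  rownames(vol) <- subjects$subject_id
  matrix_to_tbl(vol)
}

#' @export
print.gml_cohort <- function(x, ...) {
  cat("<gml_cohort>\n")
  tab <- table(x$subjects$cohort, x$subjects$group)
  print(tab)
  cat(sprintf("  %d ROI volume columns, seed %d\n",
              ncol(x$volumes) - 1L, x$config$seed))
  invisible(x)
}
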