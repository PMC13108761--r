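# Synthetic ROI atlas ---------------------------------------------------------
#
# A fixed, deterministic catalog of 196 named cortical and subcortical regions
# (paired Left/Right structures, midline structures, and hemisphere-merged
# "Sym" structures), each carrying the generative parameters the cohort
# simulator needs: a baseline volume, a log-linear age slope, a sex effect and
# a signed disease effect (positive = enlargement under disease, as for
# ventricles; negative = atrophy). The catalog is the same for every seed: it
# plays the role of an atlas, not of data.

.subcortical_bases <- function() {
  tibble::tribble(
    ~base,                     ~tissue,        ~baseline, ~delta,
    "Inf Lat Vent",            "ventricle",         350,   0.70,
    "Lateral Ventricle",       "ventricle",        7500,   0.30,
    "Thalamus",                "subcortical",      7000,  -0.18,
    "Pallidum",                "subcortical",      1500,  -0.18,
    "Putamen",                 "subcortical",      4200,  -0.18,
    "Caudate",                 "subcortical",      3500,  -0.10,
    "Amygdala",                "subcortical",      1300,  -0.13,
    "Hippocampus",             "subcortical",      3300,  -0.10,
    "Accumbens Area",          "subcortical",       450,  -0.13,
    "Ventral DC",              "subcortical",      4000,  -0.03,
    "Basal Forebrain",         "subcortical",       400,  -0.03,
    "Cerebral White Matter",   "white_matter",   220000,  -0.18,
    "Cerebellum White Matter", "white_matter",    13000,  -0.18,
    "Cerebellum Exterior",     "subcortical",     50000,  -0.08
  )
}

.cortical_bases <- function() {
  strong <- c(
    "precentral gyrus" = -0.13, "parahippocampal gyrus" = -0.10,
    "sup. temporal gyrus" = -0.08, "angular gyrus" = -0.08,
    "supramarginal gyrus" = -0.08, "occipital pole" = -0.06,
    "planum polare" = -0.06, "gyrus rectus" = -0.06,
    "sup. occipital gyrus" = -0.06, "medial orbital gyrus" = -0.06,
    "posterior orbital gyrus" = -0.06, "lateral orbital gyrus" = -0.06,
    "precentral gyrus medial segment" = -0.06
  )
  base <- c(
    "precentral gyrus", "postcentral gyrus",
    "precentral gyrus medial segment", "postcentral gyrus medial segment",
    "sup. frontal gyrus", "sup. frontal gyrus medial segment",
    "middle frontal gyrus", "opercular part of the inf. frontal gyrus",
    "orbital part of the inf. frontal gyrus",
    "triangular part of the inf. frontal gyrus", "frontal pole",
    "frontal operculum", "supplementary motor cortex",
    "anterior cingulate gyrus", "middle cingulate gyrus",
    "posterior cingulate gyrus", "anterior insula", "posterior insula",
    "central operculum", "parietal operculum", "angular gyrus",
    "supramarginal gyrus", "sup. parietal lobule", "precuneus", "cuneus",
    "calcarine cortex", "sup. occipital gyrus", "middle occipital gyrus",
    "inferior occipital gyrus", "occipital pole", "occipital fusiform gyrus",
    "lingual gyrus", "sup. temporal gyrus", "middle temporal gyrus",
    "inferior temporal gyrus", "temporal pole", "transverse temporal gyrus",
    "planum polare", "planum temporale", "fusiform gyrus",
    "parahippocampal gyrus", "entorhinal area", "gyrus rectus",
    "medial orbital gyrus", "lateral orbital gyrus", "anterior orbital gyrus",
    "posterior orbital gyrus", "medial frontal cortex", "subcallosal area",
    "paracentral lobule", "inferior parietal lobule",
    "superior frontal sulcus region", "inferior temporal sulcus region",
    "olfactory cortex", "perirhinal cortex"
  )
  stopifnot(length(base) == 55)
  i <- seq_along(base)
  tibble::tibble(
    base = base,
    tissue = "cortical",
    # deterministic spread of plausible gyral volumes, 1.5-15 cm^3
    baseline = round(4500 * exp(0.55 * sin(i * 2.39996))),
    delta = ifelse(base %in% names(strong), strong[base], NA_real_)
  )
}

.midline_rois <- function() {
  tibble::tribble(
    ~roi,                        ~tissue,        ~baseline, ~delta,
    "3rd ventricle",             "ventricle",        1100,   0.40,
    "4th ventricle",             "ventricle",        1700,   0.15,
    "Brainstem",                 "subcortical",     21000,  -0.04,
    "Optic chiasm",              "subcortical",        80,  -0.01,
    "CSF",                       "csf",            180000,   0.20,
    "Lobules I-V",               "subcortical",      9000,  -0.04,
    "Lobules VI-VII",            "subcortical",      4000,  -0.05,
    "Lobules VIII-X",            "subcortical",      6000,  -0.04,
    "Sym Cerebellum Grey Matter","subcortical",     90000,  -0.14
  )
}

#' Synthetic ROI atlas with generative parameters
#'
#' Returns the fixed catalog of (up to) 196 region names used by
#' [simulate_cohort()]: 69 bilateral pairs listed adjacently
#' (`Left <base>`, `Right <base>`), 9 midline structures and 49
#' hemisphere-merged `Sym` structures. Every region carries its baseline
#' volume (mm^3), per-year log-volume age slope, male-vs-female log effect and
#' signed disease effect at unit severity (`disease_delta` > 0 means the
#' structure enlarges under disease, as ventricles do; < 0 means atrophy).
#'
#' The catalog is deterministic and independent of any seed. When
#' `n_rois < 196` the first `n_rois` entries are returned (pairs stay
#' adjacent, so even truncation points keep Left/Right pairs intact).
#'
#' @param n_rois Number of regions, default and maximum 196.
#' @param n_subgroups Number of latent RIS subgroups for which disjoint
#'   cortical ROI blocks are reserved (attribute `subgroup_blocks`).
#' @return A tibble with columns `roi`, `side`, `base`, `tissue`, `baseline`,
#'   `age_slope`, `sex_log`, `disease_delta`, plus attributes `pairs`
#'   (tibble base/left/right) and `subgroup_blocks` (list of ROI-name vectors).
#' @export
roi_catalog <- function(n_rois = 196, n_subgroups = 4) {
  if (!is_count(n_rois) || n_rois > 196) {
    abort_config("`n_rois` must be a count between 1 and 196")
  }
  if (!is_count(n_subgroups) || n_subgroups > 9) {
    abort_config("`n_subgroups` must be a count between 1 and 9")
  }
  sub <- .subcortical_bases()
  cor <- .cortical_bases()
  bases <- dplyr::bind_rows(
    dplyr::mutate(sub, delta = .data$delta),
    cor
  )
  i <- seq_len(nrow(bases))
  u <- (sin(i * 1.23456) + 1) / 2 # deterministic per-base jitter in [0, 1]
  bases$delta <- ifelse(is.na(bases$delta), -(0.03 + 0.012 * u), bases$delta)

  paired <- tibble::tibble(
    roi = as.vector(rbind(paste("Left", bases$base), paste("Right", bases$base))),
    side = rep(c("Left", "Right"), nrow(bases)),
    base = rep(bases$base, each = 2),
    tissue = rep(bases$tissue, each = 2),
    baseline = rep(bases$baseline, each = 2),
    disease_delta = rep(bases$delta, each = 2)
  )
  # small deterministic left/right baseline asymmetry
  paired$baseline <- paired$baseline *
    exp(0.03 * sin(seq_len(nrow(paired)) * 0.7) *
          ifelse(paired$side == "Left", 1, -1))

  mid <- .midline_rois()
  sym_bases <- cor$base[1:49]
  sym_i <- seq_along(sym_bases)
  sym <- tibble::tibble(
    roi = paste("Sym", sym_bases),
    side = "Sym",
    base = sym_bases,
    tissue = "cortical",
    baseline = round(9000 * exp(0.5 * cos(sym_i * 1.9))),
    disease_delta = -(0.03 + 0.012 * (sin(sym_i * 0.77) + 1) / 2)
  )
  midline <- tibble::tibble(
    roi = mid$roi,
    side = "Mid",
    base = mid$roi,
    tissue = mid$tissue,
    baseline = mid$baseline,
    disease_delta = mid$delta
  )

  cat <- dplyr::bind_rows(paired, midline, sym)
  stopifnot(nrow(cat) == 196, !anyDuplicated(cat$roi))

  j <- seq_len(nrow(cat))
  uj <- (sin(j * 2.71828) + 1) / 2
  cat$age_slope <- ifelse(
    cat$tissue == "ventricle", 0.012 + 0.006 * uj,
    ifelse(cat$tissue == "csf", 0.010, -(0.0025 + 0.002 * uj))
  )
  cat$sex_log <- 0.02 * sin(j * 1.7)
  # disease staging: deep grey, white matter and ventricles are involved
  # early (effect linear in severity); diffuse cortical atrophy accrues late
  # (effect proportional to severity^late_stage_exponent)
  cat$stage <- ifelse(cat$tissue %in% c("ventricle", "csf", "subcortical",
                                        "white_matter") |
                        (cat$tissue == "cortical" & cat$disease_delta <= -0.06 &
                           cat$side != "Sym"),
                      "early", "late")

  cat <- cat[seq_len(n_rois), ]

  # Two reserved cortical ROI sets span the "block plane": each latent RIS
  # subgroup atrophies a fixed linear combination of the two (a trait-like
  # signature, rank-2 by construction so that a 2-D reduction can separate
  # all subgroups).
  set_a <- .cortical_bases()$base[1:3]
  set_b <- .cortical_bases()$base[4:6]
  block_sets <- list(
    A = intersect(c(paste("Left", set_a), paste("Right", set_a)), cat$roi),
    B = intersect(c(paste("Left", set_b), paste("Right", set_b)), cat$roi))
  coeffs <- subgroup_block_coeffs(n_subgroups)
  blocks <- lapply(seq_len(n_subgroups), function(g) {
    c(if (coeffs[g, 1] > 0) block_sets$A,
      if (coeffs[g, 2] > 0) block_sets$B)
  })
  pair_bases <- bases$base
  attr(cat, "pairs") <- tibble::tibble(
    base = pair_bases,
    left = paste("Left", pair_bases),
    right = paste("Right", pair_bases)
  )[paste("Left", pair_bases) %in% cat$roi &
      paste("Right", pair_bases) %in% cat$roi, ]
  attr(cat, "subgroup_blocks") <- blocks
  attr(cat, "block_sets") <- block_sets
  attr(cat, "block_coeffs") <- coeffs
  cat
}

# Per-subgroup coefficients on the two block-plane axes, well spread in 2-D
# and with norms ascending over subgroups (higher-risk subgroups carry more
# block atrophy).
subgroup_block_coeffs <- function(n_subgroups) {
  base <- rbind(c(1, 0), c(0, 1.2), c(1, 1), c(2, 1),
                c(2, 0), c(0, 2.2), c(2, 2), c(3, 1), c(1, 3))
  base[seq_len(n_subgroups), , drop = FALSE]
}
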