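# End-to-end pipeline ----------------------------------------------------------

#' Pipeline configuration
#'
#' A single structured configuration drives every stage; per-stage seeds are
#' derived from the master seed by one documented splitting rule
#' (a seeded `sample.int()` draw), so two runs with identical configuration
#' are bit-identical.
#'
#' @param cohort A [cohort_config()].
#' @param d Manifold embedding dimension.
#' @param k_neighbors Digital-twin neighbour count (default 30).
#' @param k_clusters Number of RIS risk clusters (default 4).
#' @param z_threshold Two-sided abnormality threshold (default 1.96).
#' @param risk_bands Orange/red conversion-risk band edges
#'   (default `c(0.10, 0.25)`).
#' @param n_boot Bootstrap replicates for cluster CIs.
#' @param knn_graph_k Initial neighbour count of the pseudotime graph.
#' @param trajectory_rois ROI names whose trajectories the report tabulates.
#' @param seed Master seed for all non-cohort stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       d = 10, k_neighbors = 30, k_clusters = 4,
                       z_threshold = 1.96, risk_bands = c(0.10, 0.25),
                       n_boot = 2000, knn_graph_k = 10,
                       trajectory_rois = c("3rd ventricle", "Left Thalamus",
                                           "Sym Cerebellum Grey Matter",
                                           "Left Inf Lat Vent"),
                       seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (!is_count(k_neighbors) || !is_count(k_clusters) || !is_count(d)) {
    abort_config("d, k_neighbors and k_clusters must be counts")
  }
  structure(list(cohort = cohort, d = d, k_neighbors = k_neighbors,
                 k_clusters = k_clusters, z_threshold = z_threshold,
                 risk_bands = risk_bands, n_boot = n_boot,
                 knn_graph_k = knn_graph_k, trajectory_rois = trajectory_rois,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full digital-twin analysis pipeline
#'
#' simulate -> features -> manifold fit -> twin scoring -> group statistics
#' -> RIS risk clustering -> pseudo-temporal trajectories, with a manifest
#' (configuration hash, derived stage seeds, package version) that makes
#' end-to-end determinism checkable: identical configurations give identical
#' manifests and outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all report tables are
#'   written as CSV with a header comment declaring the seed and
#'   configuration hash.
#' @return A list of class `gml_report`; see the elements documented below:
#'   `cohort_summary`, `bag` (per-group BAG summary + Kruskal-Wallis),
#'   `abnormality` (per-ROI percentages), `top_rois` (named list of
#'   comparisons), `similarity`, `risk` (a `gml_risk_report`),
#'   `membership_model`, `pseudotime`, `trajectories`, `deviations`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 4L)
  names(seeds) <- c("embedding", "kmeans", "bootstrap", "trajectory")

  cohort <- simulate_cohort(config$cohort)
  subjects <- cohort$subjects
  summary_tbl <- summarize_cohort(subjects)

  features <- build_features(cohort)
  ref_ids <- features$reference_ids
  ref_feat <- subset_features(features, ref_ids)
  model <- fit_manifold(ref_feat, subjects, d = config$d,
                        k = config$k_neighbors, seed = seeds[["embedding"]])

  clin_ids <- subjects$subject_id[subjects$cohort == "matched"]
  clin_feat <- subset_features(features, clin_ids)
  deviations <- score_subjects(model, clin_feat, subjects,
                               threshold = config$z_threshold)

  bag_kw <- kruskal_wallis(deviations$summary$bag, deviations$summary$group)
  bag_tbl <- deviations$summary |>
    dplyr::mutate(group = factor(.data$group, group_levels())) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     bag_median = median(.data$bag),
                     bag_mean = mean(.data$bag),
                     n_abnormal_median = median(.data$n_abnormal),
                     n_abnormal_mean = mean(.data$n_abnormal),
                     .groups = "drop")

  abn <- abnormality_map(deviations)
  pair_set <- list(c("HC", "RIS-NC"), c("HC", "MS"), c("HC", "RIS-C"),
                   c("RIS-NC", "MS"), c("RIS-NC", "RIS-C"), c("MS", "RIS-C"))
  top_rois <- lapply(pair_set, function(p) {
    rank_top_rois(deviations, p[1], p[2])
  })
  names(top_rois) <- vapply(pair_set, paste, "", collapse = "/")
  similarity <- column_similarity(top_rois)

  ris_ids <- subjects$subject_id[subjects$group %in% c("RIS-NC", "RIS-C")]
  coords2 <- embed_2d(deviations, ids = ris_ids, seed = seeds[["embedding"]])
  km <- cluster_kmeans(coords2, k = config$k_clusters, seed = seeds[["kmeans"]])
  risk <- risk_cluster_report(km, subjects, coords = coords2,
                              n_boot = config$n_boot,
                              seed = seeds[["bootstrap"]])
  covars <- subjects |>
    dplyr::filter(.data$subject_id %in% ris_ids) |>
    dplyr::left_join(deviations$summary[c("subject_id", "bag")],
                     by = "subject_id") |>
    dplyr::transmute(.data$subject_id, .data$age, .data$sex, .data$bag,
                     .data$lesion_load,
                     cord_lesion = .data$spinal_cord_lesion)
  membership <- tryCatch(
    multinomial_membership_model(risk$assignments, covars),
    error = function(e) NULL)

  emb <- embed_features(model, clin_feat)
  hc_ids <- subjects$subject_id[subjects$cohort == "matched" &
                                  subjects$group == "HC"]
  pt <- pseudotime_scores(emb, hc_ids, knn_k = config$knn_graph_k)
  traj <- lapply(intersect(config$trajectory_rois, deviations$roi_names),
                 function(r) fit_trajectory(pt, deviations, r,
                                            threshold = config$z_threshold))
  names(traj) <- vapply(traj, function(t) t$roi, "")
  traj_tbl <- purrr::map_dfr(traj, function(t) {
    dplyr::mutate(t$sampled, roi = t$roi, crossing = t$crossing,
                  .before = 1)
  })
  cluster_traj <- tryCatch(
    compare_cluster_trajectories(pt, deviations, risk$assignments,
                                 "Left Inf Lat Vent", n_boot = 0),
    error = function(e) NULL)

  manifest <- list(
    config_hash = rlang::hash(config),
    cohort_seed = config$cohort$seed,
    master_seed = config$seed,
    stage_seeds = as.list(seeds),
    n_subjects = nrow(subjects),
    n_rois = config$cohort$n_rois,
    knn_graph_k_used = attr(pt, "knn_k_used"),
    package_version = as.character(utils::packageVersion("gmltwin"))
  )

  report <- structure(list(
    cohort_summary = summary_tbl, bag = list(table = bag_tbl, test = bag_kw),
    abnormality = abn, top_rois = top_rois, similarity = similarity,
    risk = risk, membership_model = membership,
    pseudotime = pt, trajectories = traj_tbl, cluster_trajectories = cluster_traj,
    deviations = deviations, model = model, cohort = cohort,
    manifest = manifest, config = config
  ), class = "gml_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Cohort characteristics summary
#'
#' Group sizes, sex composition, age (mean +/- SD) per group, and the
#' RIS biomarker panel: yes/no counts among non-missing subjects and the
#' availability percentage to one decimal.
#'
#' @param subjects Subject tibble.
#' @return A list of class `gml_cohort_summary`: `groups` and `biomarkers`
#'   tibbles.
#' @export
summarize_cohort <- function(subjects) {
  if (!nrow(subjects)) abort_config("empty subject table")
  grp <- subjects |>
    dplyr::mutate(grouping = ifelse(.data$cohort %in% "reference",
                                    "HC (reference)", .data$group)) |>
    dplyr::group_by(.data$grouping) |>
    dplyr::summarise(n = dplyr::n(),
                     pct_female = round(100 * mean(.data$sex == "F"), 1),
                     age_mean = round(mean(.data$age), 1),
                     age_sd = round(sd(.data$age), 1), .groups = "drop")
  ris <- subjects[subjects$group %in% c("RIS-NC", "RIS-C"), ]
  bm_cols <- intersect(c("spinal_cord_lesion", "infratentorial_lesion",
                         "gadolinium_lesion", "csf_positive"),
                       names(subjects))
  biomarkers <- purrr::map_dfr(bm_cols, function(bm) {
    v <- ris[[bm]]
    tibble::tibble(
      biomarker = bm,
      yes = sum(v == "yes", na.rm = TRUE),
      no = sum(v == "no", na.rm = TRUE),
      available = sum(!is.na(v)),
      n_ris = nrow(ris),
      availability_pct = round(100 * sum(!is.na(v)) / max(1, nrow(ris)), 1))
  })
  structure(list(groups = grp, biomarkers = biomarkers),
            class = "gml_cohort_summary")
}

#' @export
print.gml_cohort_summary <- function(x, ...) {
  cat("<gml_cohort_summary>\n")
  print(x$groups)
  if (nrow(x$biomarkers)) print(x$biomarkers)
  invisible(x)
}

#' @export
print.gml_report <- function(x, ...) {
  cat("<gml_report>\n")
  cat(sprintf("  config hash %s\n", x$manifest$config_hash))
  print(x$bag$table)
  print(x$risk$clusters)
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Every CSV starts with a header comment declaring the generating seed and
#' configuration hash.
#'
#' @param report A `gml_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# config_hash=%s seed=%d cohort_seed=%d",
                 report$manifest$config_hash, report$manifest$master_seed,
                 report$manifest$cohort_seed)
  wr <- function(tbl, name) {
    path <- file.path(dir, name)
    writeLines(hdr, path)
    readr::write_csv(tbl, path, na = "", append = TRUE, col_names = TRUE)
  }
  wr(report$cohort_summary$groups, "cohort_groups.csv")
  wr(report$cohort_summary$biomarkers, "cohort_biomarkers.csv")
  wr(report$bag$table, "bag.csv")
  wr(report$abnormality, "abnormality_map.csv")
  for (nm in names(report$top_rois)) {
    wr(report$top_rois[[nm]],
       paste0("top10_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
  }
  wr(report$similarity, "column_similarity.csv")
  wr(report$risk$clusters, "clusters.csv")
  wr(report$risk$fisher, "cluster_fisher.csv")
  wr(report$pseudotime, "pseudotime.csv")
  wr(report$trajectories, "trajectories.csv")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
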