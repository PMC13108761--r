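# Group-level deviation statistics --------------------------------------------

#' Per-ROI abnormality percentage by group
#'
#' For every ROI and group, the percentage of subjects whose GeoNorm z-score
#' exceeds the two-sided threshold (`|z| > 1.96` by default) — the tabular
#' counterpart of a regional abnormality-burden map.
#'
#' @param deviations A `gml_deviations` from [score_subjects()].
#' @param subjects Subject tibble with `subject_id` and `group` (optional if
#'   the deviation summary already carries `group`).
#' @param threshold Two-sided threshold on |z|.
#' @return Tibble `group`, `roi`, `n`, `n_abnormal`, `pct_abnormal`.
#' @export
abnormality_map <- function(deviations, subjects = NULL, threshold = NULL) {
  threshold <- threshold %||% deviations$threshold
  groups <- resolve_groups(deviations, subjects)
  zm <- tbl_to_matrix(deviations$z)[, deviations$roi_names, drop = FALSE]
  purrr::map_dfr(split(names(groups), groups), function(ids) {
    sub <- abs(zm[ids, , drop = FALSE]) > threshold
    tibble::tibble(roi = colnames(sub), n = length(ids),
                   n_abnormal = unname(colSums(sub)),
                   pct_abnormal = unname(100 * colMeans(sub)))
  }, .id = "group")
}

resolve_groups <- function(deviations, subjects = NULL) {
  ids <- deviations$z$subject_id
  if (!is.null(subjects)) {
    g <- setNames(subjects$group, subjects$subject_id)[ids]
  } else if ("group" %in% names(deviations$summary)) {
    g <- setNames(deviations$summary$group, deviations$summary$subject_id)[ids]
  } else {
    abort_schema("no group labels available")
  }
  if (anyNA(g)) abort_schema("missing group label for scored subject(s)")
  if (any(table(g) < 1)) abort_schema("empty group")
  setNames(as.character(g), ids)
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H,
#' chi-square reference) with an explicit degenerate contract: when all
#' values are identical, `H = 0` and `p = 1`.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (>= 2 non-empty groups).
#' @return Tibble `statistic`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 1)) {
    abort_config("need at least two non-empty groups")
  }
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1, n = length(values)))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value, n = length(values))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test via [stats::wilcox.test()]: exact for small untied
#' samples, otherwise the tie-corrected normal approximation. The statistic
#' is the Mann-Whitney U for the first sample.
#'
#' @param a,b Numeric samples (both non-empty).
#' @return Tibble `u`, `p_value`, `effect` (rank-biserial correlation,
#'   positive when `a` tends larger).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) abort_config("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b))
  u <- unname(wt$statistic)
  rb <- 2 * u / (length(a) * length(b)) - 1
  tibble::tibble(u = u, p_value = wt$p.value, effect = rb)
}

#' Rank the most group-discriminative ROIs
#'
#' For a pair of groups, runs a Mann-Whitney test per ROI on GeoNorm
#' z-scores, ranks ROIs by ascending p (ties by larger |rank-biserial|
#' effect, then ROI order — deterministic), keeps the top `n_top`, and
#' labels each retained ROI's direction from the sign of the group-median
#' z difference: `increase` when the second group's median z is higher,
#' `atrophy` when lower.
#'
#' @param deviations A `gml_deviations`.
#' @param group_a,group_b Group labels to compare (direction is
#'   `median(z_b) - median(z_a)`).
#' @param subjects Optional subject tibble with group labels.
#' @param n_top Number of ROIs to keep (default 10).
#' @return A tibble of class `gml_comparison` with columns `roi`, `u`,
#'   `p_value`, `effect`, `direction`, `rank`; attributes `group_a`,
#'   `group_b`.
#' @export
rank_top_rois <- function(deviations, group_a, group_b, subjects = NULL,
                          n_top = 10) {
  groups <- resolve_groups(deviations, subjects)
  zm <- tbl_to_matrix(deviations$z)[, deviations$roi_names, drop = FALSE]
  ia <- names(groups)[groups == group_a]
  ib <- names(groups)[groups == group_b]
  if (!length(ia) || !length(ib)) abort_config("both groups must be non-empty")
  res <- purrr::map_dfr(colnames(zm), function(r) {
    za <- zm[ia, r]
    zb <- zm[ib, r]
    mw <- mann_whitney(za, zb)
    tibble::tibble(roi = r, u = mw$u, p_value = mw$p_value, effect = mw$effect,
                   direction = ifelse(median(zb) - median(za) >= 0,
                                      "increase", "atrophy"))
  })
  ord <- order(res$p_value, -abs(res$effect), seq_len(nrow(res)))
  out <- res[ord, ][seq_len(min(n_top, nrow(res))), ]
  out$rank <- seq_len(nrow(out))
  structure(out, group_a = group_a, group_b = group_b,
            class = c("gml_comparison", class(out)))
}

#' Column similarity of top-ROI sets
#'
#' Jaccard overlap of the top-ROI sets of every pair of group comparisons —
#' which structural signatures are shared across disease-stage contrasts.
#'
#' @param comparisons Named list of `gml_comparison` tibbles (or character
#'   vectors of ROI names).
#' @return Tibble `comparison_a`, `comparison_b`, `n_shared`, `jaccard` for
#'   every unordered pair.
#' @export
column_similarity <- function(comparisons) {
  if (length(comparisons) < 2) abort_config("need at least two comparisons")
  sets <- lapply(comparisons, function(x) {
    if (is.character(x)) x else x$roi
  })
  nms <- names(sets) %||% as.character(seq_along(sets))
  if (is.null(names(sets))) names(sets) <- nms
  pairs <- utils::combn(nms, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1, j]]]
    b <- sets[[pairs[2, j]]]
    shared <- length(intersect(a, b))
    tibble::tibble(comparison_a = pairs[1, j], comparison_b = pairs[2, j],
                   n_shared = shared,
                   jaccard = shared / length(union(a, b)))
  })
}
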