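# Pseudo-temporal trajectories -------------------------------------------------

#' Graph-geodesic progression scores
#'
#' Places every subject on a cross-sectional progression axis: the geodesic
#' distance from the healthy-control centroid, computed as the shortest path
#' on a symmetrised k-nearest-neighbour graph over the embedded subjects
#' plus a centroid node (edge weight = Euclidean length), then min-max
#' normalised to `[0, 1]` over the cohort. If the graph is disconnected the
#' neighbour count is increased until it connects (the value used is
#' reported); a graph still disconnected at `k_max` is an error.
#'
#' @param coords Tibble `subject_id` + embedding coordinate columns.
#' @param hc_ids Subject ids defining the healthy centroid.
#' @param knn_k Initial neighbour count for the graph (default 10).
#' @param k_max Largest neighbour count tried (default `n - 1`).
#' @return A tibble of class `gml_pseudotime`: `subject_id`, `distance`
#'   (raw geodesic), `pseudotime` (normalised); attribute `knn_k_used`.
#' @export
pseudotime_scores <- function(coords, hc_ids, knn_k = 10, k_max = NULL) {
  X <- tbl_to_matrix(coords)
  hc_ids <- intersect(hc_ids, rownames(X))
  if (!length(hc_ids)) abort_config("no healthy-control ids among the coordinates")
  centroid <- colMeans(X[hc_ids, , drop = FALSE])
  A <- rbind(X, "..centroid.." = centroid)
  n <- nrow(A)
  k_max <- k_max %||% (n - 1)
  D <- as.matrix(dist(A))

  for (k in unique(pmin(seq(knn_k, k_max, by = 5), k_max))) {
    g <- knn_graph(D, k)
    if (igraph::is_connected(g)) {
      dist_all <- igraph::distances(g, v = n)[1, ]
      d <- dist_all[seq_len(n - 1)]
      rng <- range(d)
      pt <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) else rep(0, length(d))
      out <- tibble::tibble(subject_id = rownames(X), distance = unname(d),
                            pseudotime = unname(pt))
      attr(out, "knn_k_used") <- k
      class(out) <- c("gml_pseudotime", class(tibble::tibble()))
      return(out)
    }
  }
  abort_config("k-NN graph is disconnected even at the largest neighbour count")
}

knn_graph <- function(D, k) {
  n <- nrow(D)
  k <- min(k, n - 1)
  edges <- NULL
  weights <- NULL
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    edges <- c(edges, rbind(i, nb))
    weights <- c(weights, D[i, nb])
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  igraph::E(g)$weight <- weights
  igraph::simplify(g, edge.attr.comb = "min")
}

#' Fit a smooth trajectory of one ROI's z-scores along pseudotime
#'
#' Penalised thin-plate spline smooth ([mgcv::gam()], roughness selected
#' by GCV) of GeoNorm z against the progression score, sampled at 10 equally
#' spaced pseudotimes on `[0, 1]`; the threshold crossing is the smallest
#' pseudotime at which the fitted `|z|` reaches `threshold`, refined by
#' root-finding on the smooth (absent if the smooth never crosses).
#' When fewer subjects than the basis dimension are available the basis is
#' shrunk with a warning.
#'
#' @param scores A `gml_pseudotime` tibble (or `subject_id` + `pseudotime`).
#' @param deviations A `gml_deviations` (or tibble `subject_id` + z columns).
#' @param roi ROI name to model.
#' @param k_basis Spline basis dimension (default 10).
#' @param threshold Crossing threshold on |fitted z| (default 1.96).
#' @param n_points Number of sampled trajectory points (default 10).
#' @return A list of class `gml_trajectory`: `roi`, `sampled` (tibble
#'   `point`, `pseudotime`, `z`), `crossing` (pseudotime or `NA`), `fit`,
#'   `n`, `threshold`.
#' @export
fit_trajectory <- function(scores, deviations, roi, k_basis = 10,
                           threshold = 1.96, n_points = 10) {
  z_tbl <- if (inherits(deviations, "gml_deviations")) deviations$z else deviations
  if (!roi %in% names(z_tbl)) abort_schema(sprintf("unknown ROI `%s`", roi))
  dat <- dplyr::inner_join(
    tibble::tibble(subject_id = scores$subject_id, t = scores$pseudotime),
    z_tbl[c("subject_id", roi)], by = "subject_id")
  names(dat)[3] <- "z"
  dat <- dat[is.finite(dat$z) & is.finite(dat$t), ]
  if (nrow(dat) < 20) abort_config("need at least 20 subjects to fit a trajectory")
  kb <- k_basis
  if (nrow(dat) < 3 * kb) {
    kb <- max(4, floor(nrow(dat) / 3))
    rlang::warn(sprintf("basis dimension shrunk to %d for n = %d", kb, nrow(dat)))
  }
  fit <- mgcv::gam(z ~ s(t, k = kb), data = dat, method = "GCV.Cp")

  grid <- seq(0, 1, length.out = 401)
  fz <- as.numeric(predict(fit, newdata = data.frame(t = grid)))
  tp <- seq(0, 1, length.out = n_points)
  sampled <- tibble::tibble(
    point = seq_len(n_points), pseudotime = tp,
    z = as.numeric(predict(fit, newdata = data.frame(t = tp))))

  crossing <- NA_real_
  hit <- which(abs(fz) >= threshold)
  if (length(hit)) {
    j <- hit[1]
    if (j == 1) {
      crossing <- grid[1]
    } else {
      f <- function(t) abs(as.numeric(predict(fit, newdata = data.frame(t = t)))) -
        threshold
      crossing <- uniroot(f, c(grid[j - 1], grid[j]))$root
    }
  }
  structure(list(roi = roi, sampled = sampled, crossing = crossing,
                 fit = fit, n = nrow(dat), threshold = threshold),
            class = "gml_trajectory")
}

#' Compare threshold-crossing times across clusters
#'
#' Fits a per-cluster trajectory for one ROI and reports each cluster's
#' crossing pseudotime (earlier crossing = faster progression), with a
#' subject-level bootstrap for the crossing uncertainty. Clusters whose
#' smooth never reaches the threshold inside `[0, 1]` are reported as
#' censored (`crossing = NA`).
#'
#' @param scores A `gml_pseudotime` tibble.
#' @param deviations A `gml_deviations` (or z tibble).
#' @param assignments Tibble `subject_id`, `cluster`.
#' @param roi ROI name.
#' @param n_boot Bootstrap replicates per cluster (default 100; 0 disables).
#' @param seed Integer seed for the bootstrap.
#' @param ... Passed to [fit_trajectory()].
#' @return Tibble `cluster`, `n`, `crossing`, `ci_lower`, `ci_upper`,
#'   `censored`.
#' @export
compare_cluster_trajectories <- function(scores, deviations, assignments, roi,
                                         n_boot = 100, seed = NULL, ...) {
  z_tbl <- if (inherits(deviations, "gml_deviations")) deviations$z else deviations
  with_seed(seed, {
    purrr::map_dfr(sort(unique(assignments$cluster)), function(cl) {
      ids <- assignments$subject_id[assignments$cluster == cl]
      sc <- scores[scores$subject_id %in% ids, ]
      tr <- suppressWarnings(fit_trajectory(sc, z_tbl, roi, ...))
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0) {
        boots <- vapply(seq_len(n_boot), function(b) {
          idx <- sample.int(nrow(sc), replace = TRUE)
          tb <- suppressWarnings(tryCatch(
            fit_trajectory(sc[idx, ], z_tbl, roi, ...)$crossing,
            error = function(e) NA_real_))
          tb %||% NA_real_
        }, numeric(1))
        if (any(is.finite(boots))) {
          ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
        }
      }
      tibble::tibble(cluster = cl, n = tr$n, crossing = tr$crossing,
                     ci_lower = ci[1], ci_upper = ci[2],
                     censored = is.na(tr$crossing))
    })
  })
}

#' @export
print.gml_trajectory <- function(x, ...) {
  cat(sprintf("<gml_trajectory> %s: n=%d, crossing at |z|>=%.2f: %s\n",
              x$roi, x$n, x$threshold,
              ifelse(is.na(x$crossing), "none in [0,1]",
                     sprintf("t=%.3f", x$crossing))))
  invisible(x)
}
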