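line_coords <- function(n = 10) {
  tibble::tibble(subject_id = sprintf("S%02d", seq_len(n)),
                 dim1 = as.numeric(seq_len(n) - 1), dim2 = 0)
}

test_that("geodesic distances on a line are exact and the centroid scores 0", {
  co <- line_coords(10)
  # centroid = the first point (single HC at one end)
  pt <- pseudotime_scores(co, hc_ids = "S01", knn_k = 3)
  expect_equal(pt$distance, 0:9)
  expect_equal(pt$pseudotime, (0:9) / 9)
  expect_equal(pt$pseudotime[1], 0)
  expect_true(!is.unsorted(pt$pseudotime))
})

test_that("pseudotime is invariant under rigid transformations", {
  set.seed(21)
  X <- matrix(rnorm(80), 40, 2)
  co <- tibble::tibble(subject_id = sprintf("S%02d", 1:40),
                       dim1 = X[, 1], dim2 = X[, 2])
  theta <- 0.7
  Rmat <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Y <- X %*% Rmat + 5
  co2 <- tibble::tibble(subject_id = co$subject_id,
                        dim1 = Y[, 1], dim2 = Y[, 2])
  hc <- co$subject_id[1:10]
  p1 <- pseudotime_scores(co, hc)
  p2 <- pseudotime_scores(co2, hc)
  expect_equal(p1$pseudotime, p2$pseudotime, tolerance = 1e-10)
})

test_that("a disconnected graph raises the neighbour count until connected", {
  co <- dplyr::bind_rows(line_coords(8),
                         dplyr::mutate(line_coords(8),
                                       subject_id = paste0("T", subject_id),
                                       dim1 = dim1 + 100))
  pt <- pseudotime_scores(co, hc_ids = "S01", knn_k = 2)
  expect_true(all(is.finite(pt$distance)))
  expect_gt(attr(pt, "knn_k_used"), 2)
})

test_that("trajectory smooths recover constants and noiseless lines", {
  set.seed(22)
  n <- 60
  sc <- tibble::tibble(subject_id = sprintf("S%02d", 1:n),
                       pseudotime = seq(0, 1, length.out = n))
  zc <- tibble::tibble(subject_id = sc$subject_id, roiX = rep(1.2, n))
  tr <- fit_trajectory(sc, zc, "roiX")
  expect_equal(tr$sampled$z, rep(1.2, 10), tolerance = 1e-6)
  expect_true(is.na(tr$crossing))
  expect_equal(tr$sampled$pseudotime, seq(0, 1, length.out = 10))

  zl <- tibble::tibble(subject_id = sc$subject_id, roiX = 3 * sc$pseudotime)
  trl <- fit_trajectory(sc, zl, "roiX")
  expect_equal(trl$sampled$z, 3 * seq(0, 1, length.out = 10),
               tolerance = 0.05)
  expect_equal(trl$crossing, 1.96 / 3, tolerance = 0.02)
  expect_config_error(fit_trajectory(sc[1:10, ], zc[1:10, ], "roiX"))
  expect_error(fit_trajectory(sc, zc, "missing_roi"),
               class = "gmltwin_schema_error")
})

test_that("an infinite roughness penalty collapses to the least-squares line", {
  set.seed(23)
  n <- 50
  t <- runif(n)
  z <- 1 + 2 * t + rnorm(n, sd = 0.3)
  g <- mgcv::gam(z ~ s(t, k = 10, sp = 1e9))
  l <- lm(z ~ t)
  expect_equal(as.numeric(predict(g, newdata = data.frame(t = c(0.1, 0.5, 0.9)))),
               as.numeric(predict(l, newdata = data.frame(t = c(0.1, 0.5, 0.9)))),
               tolerance = 1e-3)
})

test_that("cluster crossing order recovers planted onsets; identical clusters tie", {
  set.seed(24)
  n <- 50
  mk <- function(tag, slope) {
    sc <- tibble::tibble(subject_id = sprintf("%s%02d", tag, 1:n),
                         pseudotime = seq(0, 1, length.out = n))
    z <- tibble::tibble(subject_id = sc$subject_id,
                        roiX = slope * sc$pseudotime + rnorm(n, sd = 0.15))
    list(sc = sc, z = z)
  }
  a <- mk("A", 4); b <- mk("B", 2.5)
  scores <- dplyr::bind_rows(a$sc, b$sc)
  z <- dplyr::bind_rows(a$z, b$z)
  asn <- tibble::tibble(subject_id = scores$subject_id,
                        cluster = rep(1:2, each = n))
  ct <- compare_cluster_trajectories(scores, z, asn, "roiX",
                                     n_boot = 50, seed = 1)
  expect_false(any(ct$censored))
  expect_lt(ct$crossing[1], ct$crossing[2]) # steeper planted onset crosses first
  expect_equal(ct$crossing[1], 1.96 / 4, tolerance = 0.08)
  expect_equal(ct$crossing[2], 1.96 / 2.5, tolerance = 0.08)

  # exchangeable clusters: bootstrap intervals overlap
  b2 <- mk("C", 4)
  scores2 <- dplyr::bind_rows(a$sc, b2$sc)
  z2 <- dplyr::bind_rows(a$z, b2$z)
  asn2 <- tibble::tibble(subject_id = scores2$subject_id,
                         cluster = rep(1:2, each = n))
  ct2 <- compare_cluster_trajectories(scores2, z2, asn2, "roiX",
                                      n_boot = 80, seed = 2)
  expect_true(ct2$ci_lower[1] <= ct2$ci_upper[2] &&
                ct2$ci_lower[2] <= ct2$ci_upper[1])
})

test_that("planted severity raises the fitted end of every perturbed ROI", {
  fix <- get_small_pipeline()
  coh <- fix$cohort
  emb <- embed_features(fix$model,
                        subset_features_t(fix$features,
                                          fix$deviations$z$subject_id))
  hc <- coh$subjects$subject_id[coh$subjects$cohort == "matched" &
                                  coh$subjects$group == "HC"]
  pt <- pseudotime_scores(emb, hc)
  for (roi in c("3rd ventricle", "Left Inf Lat Vent")) {
    tr <- fit_trajectory(pt, fix$deviations, roi)
    expect_gt(tr$sampled$z[10], tr$sampled$z[1])
  }
})
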