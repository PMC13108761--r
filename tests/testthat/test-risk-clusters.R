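test_that("Fisher exact 2x2 matches enumerated references", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70)
  expect_config_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)))
  expect_config_error(fisher_exact_2x2(matrix(c(0.5, 1, 1, 1), 2)))
  # independent oracle: stats::fisher.test on random tables
  set.seed(4)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("pairwise cluster tests build the right 2x2 tables", {
  asn <- tibble::tibble(subject_id = sprintf("S%02d", 1:16),
                        cluster = rep(1:2, each = 8))
  out <- tibble::tibble(subject_id = asn$subject_id,
                        converted = c(rep(TRUE, 3), rep(FALSE, 5),
                                      rep(TRUE, 1), rep(FALSE, 7)))
  pw <- pairwise_cluster_tests(asn, out)
  expect_equal(pw$p_value,
               fisher_exact_2x2(rbind(c(3, 5), c(1, 7))))
})

test_that("risk labels follow the red/orange band edges inclusively", {
  expect_equal(label_risk(c(0.39, 0.25, 0.249, 0.10, 0.09)),
               c("red", "red", "orange", "orange", "low"))
  expect_config_error(label_risk(1.2))
})

test_that("conversion rates and degenerate bootstrap intervals", {
  asn <- tibble::tibble(subject_id = sprintf("S%d", 1:8), cluster = 1L)
  out <- tibble::tibble(subject_id = asn$subject_id,
                        converted = c(TRUE, TRUE, rep(FALSE, 6)))
  cr <- conversion_rates(asn, out, n_boot = 200, seed = 1)
  expect_equal(cr$rate, 0.25)
  expect_equal(cr$converters, 2)
  all_conv <- conversion_rates(asn, dplyr::mutate(out, converted = TRUE),
                               n_boot = 200, seed = 1)
  expect_equal(all_conv$rate, 1)
  expect_equal(c(all_conv$ci_lower, all_conv$ci_upper), c(1, 1))
  tiny <- conversion_rates(asn[1:4, ], out[1:4, ], n_boot = 100, seed = 1)
  expect_true(tiny$unstable)
})

test_that("k-means recovers planted blobs and is deterministic", {
  set.seed(8)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  truth <- rep(1:4, each = 25)
  X <- centers[truth, ] + matrix(rnorm(200, sd = 0.7), 100, 2)
  coords <- tibble::tibble(subject_id = sprintf("S%03d", 1:100),
                           dim1 = X[, 1], dim2 = X[, 2])
  km <- cluster_kmeans(coords, k = 4, seed = 5)
  expect_gte(mclust::adjustedRandIndex(km$cluster, truth), 0.9)
  km2 <- cluster_kmeans(coords, k = 4, seed = 5)
  expect_identical(km, km2)
  one <- cluster_kmeans(coords, k = 1, seed = 5)
  expect_equal(unique(one$cluster), 1L)
  expect_config_error(cluster_kmeans(coords[1:6, ], k = 4))
})

test_that("the risk report is invariant to k-means label permutation", {
  set.seed(9)
  n <- 60
  asn <- tibble::tibble(subject_id = sprintf("S%02d", 1:n),
                        cluster = rep(1:3, each = 20))
  subj <- tibble::tibble(
    subject_id = asn$subject_id,
    converted = rbinom(n, 1, c(0.4, 0.05, 0.2)[asn$cluster]) == 1,
    spinal_cord_lesion = sample(c("yes", "no"), n, replace = TRUE),
    infratentorial_lesion = "no", gadolinium_lesion = "no",
    csf_positive = "yes")
  r1 <- risk_cluster_report(asn, subj, n_boot = 200, seed = 2)
  perm <- c(3L, 1L, 2L)
  asn2 <- dplyr::mutate(asn, cluster = perm[cluster])
  r2 <- risk_cluster_report(asn2, subj, n_boot = 200, seed = 2)
  expect_equal(r1$clusters, r2$clusters)
  expect_equal(r1$fisher, r2$fisher)
  expect_equal(r1$assignments$cluster, r2$assignments$cluster)
  # renumbering is ascending in conversion rate
  expect_true(!is.unsorted(r1$clusters$rate))
})

test_that("biomarker enrichment detects a planted cluster association", {
  set.seed(10)
  n <- 152
  asn <- tibble::tibble(subject_id = sprintf("S%03d", 1:n),
                        cluster = rep(1:4, length.out = n))
  p_cord <- c(0.05, 0.7, 0.7, 0.05)[asn$cluster]
  subj <- tibble::tibble(
    subject_id = asn$subject_id,
    spinal_cord_lesion = ifelse(rbinom(n, 1, p_cord) == 1, "yes", "no"),
    infratentorial_lesion = "no",
    gadolinium_lesion = ifelse(rbinom(n, 1, 0.2) == 1, "yes", "no"),
    csf_positive = NA_character_)
  be <- biomarker_enrichment(asn, subj)
  expect_lt(be$tests$p_value[be$tests$biomarker == "spinal_cord_lesion"], 0.05)
  # constant biomarker: p = 1
  expect_equal(be$tests$p_value[be$tests$biomarker == "infratentorial_lesion"], 1)
  # all-missing biomarker: degenerate with availability 0
  expect_equal(be$tests$method[be$tests$biomarker == "csf_positive"],
               "degenerate")
  expect_equal(sum(be$rates$n_available[be$rates$biomarker == "csf_positive"]), 0)
  # availability denominator counts non-missing subjects only
  expect_equal(sum(be$rates$n_available[
    be$rates$biomarker == "spinal_cord_lesion"]), n)
})

test_that("multinomial membership model honours its null and planted cases", {
  set.seed(11)
  n <- 240
  cl <- rep(1:3, each = n / 3)
  # intercept-only: predicted probabilities reproduce cluster frequencies
  asn <- tibble::tibble(subject_id = sprintf("S%03d", 1:n), cluster = cl)
  cov0 <- tibble::tibble(subject_id = asn$subject_id, junk = 1)
  fit0 <- multinomial_membership_model(
    asn, dplyr::select(cov0, "subject_id"))
  probs <- predict(fit0$fit, newdata = data.frame(row = 1), type = "probs")
  expect_equal(unname(probs), unname(table(cl) / n), tolerance = 1e-4,
               ignore_attr = TRUE)

  # independent covariates: slope z-statistics stay small
  covn <- tibble::tibble(subject_id = asn$subject_id, age = rnorm(n, 45, 10),
                         bag = rnorm(n))
  fitn <- multinomial_membership_model(asn, covn)
  slopes <- fitn$coefficients[fitn$coefficients$term != "(Intercept)", ]
  expect_lt(mean(abs(slopes$statistic) > 1.96), 0.3)
  expect_true(fitn$converged)

  # planted effect: higher bag pushes subjects into cluster 3
  bag <- rnorm(n)
  cl2 <- 1L + rbinom(n, 1, stats::plogis(-1 + 2 * bag)) +
    rbinom(n, 1, stats::plogis(-1 + 2 * bag))
  asn2 <- tibble::tibble(subject_id = asn$subject_id, cluster = cl2)
  cov2 <- tibble::tibble(subject_id = asn$subject_id, bag = bag)
  fit2 <- multinomial_membership_model(asn2, cov2)
  est <- fit2$coefficients
  expect_true(all(est$estimate[est$term == "bag"] > 0))
})

test_that("2-D reduction keeps duplicates coincident and blobs separable", {
  set.seed(12)
  z <- rbind(matrix(rnorm(40 * 20), 40, 20),
             matrix(rnorm(40 * 20, 6), 40, 20))
  z <- rbind(z, z[1, , drop = FALSE]) # duplicate of row 1
  rownames(z) <- sprintf("S%03d", seq_len(nrow(z)))
  colnames(z) <- paste0("roi", 1:20)
  co <- embed_2d(toy_deviations(z))
  X <- gmltwin:::tbl_to_matrix(co)
  expect_lt(sqrt(sum((X[81, ] - X[1, ])^2)), 1e-8)
  blob <- rep(c(1, 2), each = 40)
  # a centroid classifier in 2-D separates the planted blobs
  m1 <- colMeans(X[1:40, ]); m2 <- colMeans(X[41:80, ])
  pred <- ifelse(colSums((t(X[1:80, ]) - m1)^2) <
                   colSums((t(X[1:80, ]) - m2)^2), 1, 2)
  expect_gte(mean(pred == blob), 0.95)
  co2 <- embed_2d(toy_deviations(z))
  expect_identical(co, co2)
  expect_config_error(embed_2d(toy_deviations(z[1:3, ])))
})
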