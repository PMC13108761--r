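# RIS risk clustering ----------------------------------------------------------

#' Two-dimensional reduction of deviation profiles
#'
#' Deterministic PCA of the per-ROI z-profiles to 2 dimensions (component
#' signs fixed), used as the clustering space for RIS risk stratification.
#'
#' @param deviations A `gml_deviations`, or a tibble/matrix of profiles with
#'   a `subject_id` column.
#' @param ids Optional subject ids to embed (e.g. the RIS subjects).
#' @param d Output dimension (default 2).
#' @param seed Accepted for interface stability; the reduction is
#'   deterministic.
#' @return Tibble `subject_id`, `dim1`, ..., `dimd`.
#' @export
embed_2d <- function(deviations, ids = NULL, d = 2, seed = NULL) {
  m <- if (inherits(deviations, "gml_deviations")) {
    tbl_to_matrix(deviations$z)[, deviations$roi_names, drop = FALSE]
  } else if (is.data.frame(deviations)) {
    tbl_to_matrix(deviations)
  } else {
    deviations
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(m))
    if (length(miss)) abort_schema("unknown subject id(s)")
    m <- m[ids, , drop = FALSE]
  }
  if (nrow(m) < 2 * d) {
    abort_config("too few subjects for the requested reduction")
  }
  d_eff <- min(d, ncol(m), nrow(m) - 1)
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = d_eff)
  E <- sweep(m, 2, pc$center, "-") %*% fix_signs(pc$rotation)
  colnames(E) <- paste0("dim", seq_len(ncol(E)))
  matrix_to_tbl(E)
}

#' K-means clustering of embedded coordinates
#'
#' Best of `n_init` random starts by within-cluster sum of squares,
#' deterministic given `seed`. Raw k-means labels are arbitrary; renumbering
#' by conversion rate happens in [risk_cluster_report()].
#'
#' @param coords Tibble `subject_id` + coordinate columns.
#' @param k Number of clusters (default 4; needs `k <= n/2`).
#' @param seed Integer seed.
#' @param n_init Number of random starts (default 25).
#' @return Tibble `subject_id`, `cluster` (integer 1..k).
#' @export
cluster_kmeans <- function(coords, k = 4, seed = NULL, n_init = 25) {
  X <- tbl_to_matrix(coords)
  if (!is_count(k) || k > nrow(X) / 2) {
    abort_config("`k` must be a count with k <= n/2")
  }
  km <- with_seed(seed, kmeans(X, centers = k, nstart = n_init, iter.max = 100))
  tibble::tibble(subject_id = rownames(X), cluster = as.integer(km$cluster))
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Direct hypergeometric enumeration: with margins fixed, the two-sided
#' p-value is the sum of the probabilities of all tables whose probability
#' does not exceed the observed table's (the common two-sided convention;
#' a relative tolerance of 1e-7 guards the <= against rounding). No
#' approximation is involved.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)) # 34/70
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) abort_config("need a 2x2 table")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    abort_config("table cells must be non-negative integers")
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 + r2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pairwise Fisher tests of converter counts between clusters
#'
#' For every unordered cluster pair, a 2x2 table (converted yes/no by
#' cluster) tested with [fisher_exact_2x2()].
#'
#' @param assignments Tibble `subject_id`, `cluster`.
#' @param outcomes Logical conversion outcome, named by subject_id or a
#'   tibble with `subject_id` and `converted`.
#' @return Tibble `cluster_a`, `cluster_b`, `p_value` (upper triangle).
#' @export
pairwise_cluster_tests <- function(assignments, outcomes) {
  conv <- resolve_outcomes(outcomes, assignments$subject_id)
  cl <- sort(unique(assignments$cluster))
  pairs <- utils::combn(cl, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ina <- assignments$cluster == a
    inb <- assignments$cluster == b
    tab <- rbind(c(sum(conv[ina]), sum(!conv[ina])),
                 c(sum(conv[inb]), sum(!conv[inb])))
    tibble::tibble(cluster_a = a, cluster_b = b,
                   p_value = fisher_exact_2x2(tab))
  })
}

resolve_outcomes <- function(outcomes, ids) {
  if (is.data.frame(outcomes)) {
    outcomes <- setNames(outcomes$converted, outcomes$subject_id)
  }
  conv <- if (!is.null(names(outcomes))) outcomes[ids] else outcomes
  if (length(conv) != length(ids) || anyNA(conv)) {
    abort_schema("every subject needs a non-missing conversion outcome")
  }
  as.logical(conv)
}

#' Cluster conversion rates with percentile-bootstrap 95% CIs
#'
#' Rate = converters / cluster size; the CI resamples subjects within each
#' cluster (`n_boot` replicates, percentile 2.5/97.5). Clusters smaller than
#' 5 are flagged unstable.
#'
#' @param assignments Tibble `subject_id`, `cluster`.
#' @param outcomes See [pairwise_cluster_tests()].
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the resampling.
#' @return Tibble `cluster`, `n`, `converters`, `rate`, `ci_lower`,
#'   `ci_upper`, `unstable`.
#' @export
conversion_rates <- function(assignments, outcomes, n_boot = 2000,
                             seed = NULL) {
  conv <- resolve_outcomes(outcomes, assignments$subject_id)
  with_seed(seed, {
    purrr::map_dfr(sort(unique(assignments$cluster)), function(cl) {
      x <- conv[assignments$cluster == cl]
      n <- length(x)
      boot <- rowMeans(matrix(sample(x, n * n_boot, replace = TRUE),
                              nrow = n_boot))
      ci <- unname(quantile(boot, c(0.025, 0.975)))
      tibble::tibble(cluster = cl, n = n, converters = sum(x),
                     rate = mean(x), ci_lower = ci[1], ci_upper = ci[2],
                     unstable = n < 5)
    })
  })
}

#' Risk labels from conversion rates
#'
#' `red` when rate >= 25% (inclusive), `orange` for 10-25%, `low` below 10%.
#'
#' @param rates Numeric conversion rates in `[0, 1]`.
#' @return Character vector of labels.
#' @export
label_risk <- function(rates) {
  if (any(rates < 0 | rates > 1, na.rm = TRUE)) {
    abort_config("rates must lie in [0, 1]")
  }
  ifelse(rates >= 0.25, "red", ifelse(rates >= 0.10, "orange", "low"))
}

#' Biomarker rates per cluster with cross-cluster exact tests
#'
#' Missing biomarkers are excluded per biomarker with counts reported
#' (availability is subject-level in the generator, mirroring a jointly
#' missing panel). Each biomarker is tested across clusters with a K x 2
#' exact test ([stats::fisher.test()], network enumeration); when that is
#' infeasible the chi-square test is used and flagged.
#'
#' @param assignments Tibble `subject_id`, `cluster`.
#' @param subjects Subject tibble carrying the biomarker columns.
#' @param biomarkers Biomarker column names.
#' @return List: `rates` (tibble biomarker x cluster: `n_positive`,
#'   `n_available`, `rate`), `tests` (tibble `biomarker`, `p_value`,
#'   `method`).
#' @export
biomarker_enrichment <- function(assignments, subjects,
                                 biomarkers = c("spinal_cord_lesion",
                                                "infratentorial_lesion",
                                                "gadolinium_lesion",
                                                "csf_positive")) {
  sub <- subjects[match(assignments$subject_id, subjects$subject_id), ]
  out_rates <- list()
  out_tests <- list()
  for (bm in biomarkers) {
    v <- sub[[bm]]
    ok <- !is.na(v)
    pos <- v == "yes"
    rates <- purrr::map_dfr(sort(unique(assignments$cluster)), function(cl) {
      inc <- assignments$cluster == cl & ok
      tibble::tibble(biomarker = bm, cluster = cl,
                     n_positive = sum(pos[inc]), n_available = sum(inc),
                     rate = ifelse(sum(inc) > 0, mean(pos[inc]), NA_real_))
    })
    out_rates[[bm]] <- rates
    if (sum(ok) == 0 || length(unique(pos[ok])) < 2) {
      out_tests[[bm]] <- tibble::tibble(biomarker = bm, p_value = 1,
                                        method = "degenerate")
    } else {
      tab <- table(assignments$cluster[ok], factor(pos[ok], c(TRUE, FALSE)))
      res <- tryCatch(
        tibble::tibble(biomarker = bm, p_value = fisher.test(tab)$p.value,
                       method = "fisher"),
        error = function(e) tibble::tibble(
          biomarker = bm,
          p_value = suppressWarnings(chisq.test(tab)$p.value),
          method = "chisq_fallback"))
      out_tests[[bm]] <- res
    }
  }
  list(rates = dplyr::bind_rows(out_rates), tests = dplyr::bind_rows(out_tests))
}

#' Multinomial model of cluster membership
#'
#' Maximum-likelihood multinomial logistic regression
#' ([nnet::multinom()]) of cluster membership on subject covariates
#' (complete cases; cluster 1 is the reference). Coefficients are reported
#' with standard errors, Wald z and p-values; non-convergence and suspected
#' separation (runaway coefficients / standard errors) are flagged.
#'
#' @param assignments Tibble `subject_id`, `cluster`.
#' @param covariates Tibble with `subject_id` and covariate columns (e.g.
#'   age, sex, bag, lesion_load, spinal_cord_lesion).
#' @return A list of class `gml_multinom`: `coefficients` (tidy tibble:
#'   `cluster`, `term`, `estimate`, `std_error`, `statistic`, `p_value`),
#'   `converged`, `separation`, `n`, `fit`.
#' @export
multinomial_membership_model <- function(assignments, covariates) {
  dat <- dplyr::inner_join(assignments, covariates, by = "subject_id")
  dat$subject_id <- NULL
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 2) abort_config("too few complete cases")
  dat$cluster <- factor(dat$cluster)
  fml <- if (ncol(dat) > 1) cluster ~ . else cluster ~ 1
  fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 500)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(dat$cluster)[2],
                                                     names(cf)))
  se <- tryCatch({
    v <- vcov(fit)
    # a non-PD Hessian (separation) yields NaN here; flagged below
    matrix(suppressWarnings(sqrt(diag(v))), nrow = nrow(cf), byrow = TRUE,
           dimnames = dimnames(cf))
  }, error = function(e) cf * NA)
  tidy_cf <- purrr::map_dfr(rownames(cf), function(cl) {
    tibble::tibble(cluster = cl, term = colnames(cf),
                   estimate = cf[cl, ], std_error = se[cl, ],
                   statistic = cf[cl, ] / se[cl, ],
                   p_value = 2 * pnorm(-abs(cf[cl, ] / se[cl, ])))
  })
  separation <- any(abs(cf) > 15, na.rm = TRUE) ||
    any(se > 30, na.rm = TRUE) || anyNA(se)
  structure(list(coefficients = tidy_cf,
                 converged = fit$convergence == 0,
                 separation = separation, n = nrow(dat), fit = fit),
            class = "gml_multinom")
}

#' Consolidated RIS risk-cluster report
#'
#' Renumbers k-means clusters by ascending conversion rate (so the whole
#' report is invariant to k-means label permutation), then assembles
#' conversion rates with bootstrap CIs, risk labels (red >= 25%,
#' orange 10-25%), pairwise Fisher exact p-values and per-cluster biomarker
#' rates with enrichment tests.
#'
#' @param assignments Tibble `subject_id`, `cluster` from
#'   [cluster_kmeans()].
#' @param subjects Subject tibble carrying `converted` and biomarkers.
#' @param coords Optional 2-D coordinates (stored for plotting).
#' @param n_boot Bootstrap replicates for the CIs.
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `gml_risk_report`: `clusters`, `fisher`,
#'   `biomarkers`, `assignments` (renumbered), `coords`.
#' @export
risk_cluster_report <- function(assignments, subjects, coords = NULL,
                                n_boot = 2000, seed = NULL) {
  conv <- resolve_outcomes(
    subjects[c("subject_id", "converted")], assignments$subject_id)
  raw_rate <- tapply(conv, assignments$cluster, mean)
  ord <- order(raw_rate, as.integer(names(raw_rate)))
  relabel <- setNames(seq_along(ord), names(raw_rate)[ord])
  assignments$cluster <- unname(relabel[as.character(assignments$cluster)])

  rates <- conversion_rates(assignments, subjects[c("subject_id", "converted")],
                            n_boot = n_boot, seed = seed)
  rates$risk_label <- label_risk(rates$rate)
  fisher <- pairwise_cluster_tests(assignments,
                                   subjects[c("subject_id", "converted")])
  bm <- biomarker_enrichment(assignments, subjects)
  structure(list(clusters = rates, fisher = fisher, biomarkers = bm,
                 assignments = assignments, coords = coords),
            class = "gml_risk_report")
}

#' @export
print.gml_risk_report <- function(x, ...) {
  cat("<gml_risk_report>\n")
  print(x$clusters)
  invisible(x)
}
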