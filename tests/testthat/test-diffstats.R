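test_that("moderated t reproduces the posterior-shrinkage hand calculation", {
  # groups (c, c +/- 0.5) vs (c + 1, ...) give pooled s2 = 0.25, dg = 4
  m <- rbind(c(1 - 0.5, 1, 1 + 0.5, 2 - 0.5, 2, 2 + 0.5))
  qm <- qm_from_matrix(m)
  design <- design_for(3, 3)
  fit <- fit_moderated_t(qm, design, prior = list(d0 = 4, s0_sq = 0.25))
  # posterior variance stays 0.25; t = 1 / sqrt(0.25 * 2/3), df = 4 + 4
  expect_equal(abs(fit$t), 2.4495, tolerance = 1e-4)
  expect_equal(fit$df_total, 8)
  expect_equal(fit$log2fc, -1)
  expect_equal(fit$ratio, 0.5)
  expect_equal(fit$direction, "Down")
})

test_that("moderated t has the ordinary-t and fixed-variance limits", {
  set.seed(61)
  m <- matrix(rnorm(100 * 9, sd = 0.4), 100, 9)
  qm <- qm_from_matrix(m)
  design <- design_for(5, 4)
  # d0 = 0: ordinary pooled two-sample t
  fit0 <- fit_moderated_t(qm, design, prior = list(d0 = 0, s0_sq = 1))
  ord <- apply(m, 1, function(r) {
    unname(stats::t.test(r[1:5], r[6:9], var.equal = TRUE)$statistic)
  })
  expect_equal(fit0$t, ord, tolerance = 1e-12)
  # d0 = Inf: z-like statistic with the fixed prior variance
  s0 <- 0.17
  fitI <- fit_moderated_t(qm, design, prior = list(d0 = Inf, s0_sq = s0))
  zlike <- (rowMeans(m[, 1:5]) - rowMeans(m[, 6:9])) /
    sqrt(s0 * (1 / 5 + 1 / 4))
  expect_equal(fitI$t, zlike, tolerance = 1e-12)
  expect_true(all(is.infinite(fitI$df_total)))
})

test_that("moderated t agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(62)
  n <- 300
  sds <- sqrt(0.04 * stats::rchisq(n, df = 5) / 5)
  m <- matrix(stats::rnorm(n * 9), n, 9) * sds
  m[, 1:5] <- m[, 1:5] + rep(c(rep(0, n * 0.9), rep(0.8, n * 0.1)), 5)
  qm <- qm_from_matrix(m)
  design <- design_for(5, 4)
  fit <- fit_moderated_t(qm, design)
  dm <- stats::model.matrix(~ 0 + factor(design$group,
                                         levels = c("case", "control")))
  colnames(dm) <- c("case", "control")
  lf <- limma::contrasts.fit(limma::lmFit(m, dm),
                             limma::makeContrasts(case - control, levels = dm))
  eb <- limma::eBayes(lf)
  expect_equal(attr(fit, "prior")$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(attr(fit, "prior")$s0_sq, eb$s2.prior, tolerance = 1e-8)
  expect_equal(fit$t, unname(eb$t[, 1]), tolerance = 1e-10)
  expect_equal(fit$p, unname(eb$p.value[, 1]), tolerance = 1e-10)
})

test_that("BH q-values agree with a hand step-up oracle", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_qvalues(rep(1, 4)), rep(1, 4))
  expect_equal(bh_qvalues(0.2), 0.2)
  expect_equal(bh_qvalues(numeric(0)), numeric(0))
  step_up <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- p[ord] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(ord)]
  }
  set.seed(71)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_qvalues(p)
    expect_equal(q, step_up(p))
    expect_true(all(q >= p))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_qvalues(p[perm]), q[perm])
  }
})

test_that("plain t-tests match hand calculations and flag degeneracy", {
  same <- two_sample_t(rep(c(3, 3, 3, 5, 5, 5), 1), rep(c("a", "b"), each = 3))
  expect_true(same$degenerate)
  ident <- two_sample_t(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  tt <- two_sample_t(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(abs(tt$t), 3.674, tolerance = 1e-3)
})

test_that("serum PSA summary statistics do not separate the groups", {
  # group means 7.17 +/- 3.02 vs 8.02 +/- 7.30 ng/ml, n = 6 each
  pca_psa <- vector_with_moments(6, 7.17, 3.02)
  bph_psa <- vector_with_moments(6, 8.02, 7.30)
  res <- two_sample_t(c(pca_psa, bph_psa), rep(c("PCa", "BPH"), each = 6),
                      welch = TRUE)
  expect_gte(res$p, 0.05)
})

test_that("null cohorts give uniform p-values", {
  cohort <- simulate_cohort(cohort_config(
    n_features = c(intact_N = 2000, desialo_O = 5),
    outlier_channel = NULL, missing_rate = 0, seed = 81))
  qm <- quantify_psms(cohort$psm$intact_N)
  fit <- fit_moderated_t(qm, cohort$design)
  ks <- stats::ks.test(fit$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("glycan-class summaries are channel-wise proportions", {
  qm <- tibble::tibble(
    feature_id = c("a", "b"),
    composition = c("HexNAc(2)Hex(9)", "HexNAc(2)Hex(2)"),
    `126` = c(100, 100), `127N` = c(80, 80),
    `129N` = c(50, 50), `129C` = c(10, 10))
  design <- tibble::tibble(channel = c("126", "127N", "129N", "129C"),
                           group = c("case", "case", "control", "control"))
  out <- suppressWarnings(summarize_glyco_classes(qm, design))
  expect_true(all(abs(out$abundance$fraction - 0.5) < 1e-12))
  sums <- tapply(out$abundance$fraction, out$abundance$channel, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("a planted fucosylated enrichment in cases is detected", {
  set.seed(91)
  comps <- c(rep("HexNAc(4)Hex(5)Fuc(1)NeuAc(1)", 10),
             rep("HexNAc(4)Hex(5)NeuAc(2)", 10))
  n_ch <- 8
  m <- matrix(2^(rnorm(20 * n_ch, 20, 0.2)), 20, n_ch)
  m[1:10, 1:4] <- m[1:10, 1:4] * 1.8  # Fuc-bearing features up in cases
  qm <- qm_from_matrix(m, log2_scale = FALSE)
  qm$composition <- comps
  design <- design_for(4, 4)
  out <- suppressWarnings(summarize_glyco_classes(qm, design))
  fuc_sia <- out$tests[out$tests$glycan_class == "C/H+Fuc/Sia", ]
  expect_lt(fuc_sia$p, 0.05)
})
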