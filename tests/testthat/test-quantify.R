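make_psm <- function(n = 3, composition = "HexNAc(4)Hex(5)NeuAc(1)") {
  tibble::tibble(
    spectrum_id = paste0("s", seq_len(n)),
    peptide = "TAVNCSSDFDACLITK", mods = "tmt",
    composition = composition, charge = 3L,
    score = 300 + seq_len(n), pep2d = 1e-4, pif = 0.95, decoy = FALSE,
    rt = 30, `126` = c(100, 50, rep(10, max(0, n - 2)))[seq_len(n)],
    `127N` = 50, `128N` = 10, `129N` = 5
  )
}

test_that("PSM tables round-trip through the tabular dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(make_psm(3), path)
  got <- read_psm_table(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$composition[1], "HexNAc(4)Hex(5)NeuAc(1)")
  expect_equal(unlist(parse_composition(got$composition[1])),
               c(hexnac = 4L, hex = 5L, fuc = 0L, neuac = 1L, neugc = 0L))
})

test_that("missing columns and bad compositions are reported with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  broken <- dplyr::select(make_psm(2), -"pif")
  readr::write_tsv(broken, path)
  expect_error(read_psm_table(path), "pif")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  bad <- make_psm(2)
  bad$composition[2] <- "HexNAc(2)Pent(9)"
  readr::write_tsv(bad, path2)
  expect_error(read_psm_table(path2), "row 2")
})

test_that("PIF and PEP-2D gates are strict at the boundary", {
  psm <- tibble::tibble(pif = c(0.80, 0.75, 0.60), pep2d = 1e-4)
  expect_equal(filter_psms(psm)$pif, 0.80)
  psm2 <- tibble::tibble(pif = 0.9, pep2d = c(0.0005, 0.001))
  expect_equal(filter_psms(psm2)$pep2d, 0.0005)
  # non-modified class (NA pep2d) exempt from the PEP gate
  psm3 <- tibble::tibble(pif = 0.9, pep2d = NA_real_)
  expect_equal(nrow(filter_psms(psm3)), 1)
  expect_equal(nrow(filter_psms(psm[0, ])), 0)
  # identification-level filtering skips the PIF gate
  expect_equal(nrow(filter_psms(psm, pif_min = NULL)), 3)
})

test_that("target-decoy filtering agrees with brute force over cutoffs", {
  psm <- tibble::tibble(score = c(0.9, 0.8, 0.6, 0.7),
                        decoy = c(FALSE, FALSE, FALSE, TRUE))
  kept <- fdr_filter(psm, 0)
  expect_setequal(kept$score, c(0.9, 0.8))
  # no decoys: all targets kept
  no_decoy <- tibble::tibble(score = c(0.5, 0.1), decoy = FALSE)
  expect_equal(nrow(fdr_filter(no_decoy, 0)), 2)
  # all decoys outscore all targets
  swamped <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1),
                            decoy = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(fdr_filter(swamped, 0)), 0)
  # brute-force oracle: best cutoff maximising kept targets at FDR <= alpha
  oracle <- function(psm, alpha) {
    cuts <- sort(unique(psm$score))
    best <- 0
    for (s in cuts) {
      nt <- sum(!psm$decoy & psm$score >= s)
      nd <- sum(psm$decoy & psm$score >= s)
      if (nt > 0 && nd / nt <= alpha) best <- max(best, nt)
    }
    best
  }
  set.seed(41)
  for (i in 1:30) {
    rnd <- tibble::tibble(score = round(stats::runif(25), 2),
                          decoy = stats::runif(25) < 0.3)
    for (alpha in c(0, 0.05, 0.2)) {
      expect_equal(nrow(fdr_filter(rnd, alpha)), oracle(rnd, alpha),
                   info = paste("alpha", alpha, "iter", i))
    }
  }
})

test_that("aggregation sums redundant PSMs and is order-independent", {
  psm <- make_psm(2)
  agg <- aggregate_to_features(psm)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$`126`, 150)
  expect_equal(agg$n_psm, 2)
  # single PSM aggregates to itself
  one <- aggregate_to_features(make_psm(1))
  expect_equal(one$`126`, 100)
  # glycoforms of one peptide stay distinct
  two_forms <- dplyr::bind_rows(make_psm(1),
                                make_psm(1, "HexNAc(5)Hex(6)Fuc(1)NeuAc(3)"))
  expect_equal(nrow(aggregate_to_features(two_forms)), 2)
  # charge states merge into one feature
  mixed_z <- make_psm(2)
  mixed_z$charge <- c(2L, 3L)
  expect_equal(nrow(aggregate_to_features(mixed_z)), 1)
  # permutation invariance
  cohort <- simulate_cohort(cohort_config(
    n_features = c(intact_N = 40, desialo_O = 5), seed = 13))
  tab <- cohort$psm$intact_N
  a <- aggregate_to_features(tab)
  b <- aggregate_to_features(tab[sample(nrow(tab)), ])
  expect_equal(a, b)
})

test_that("normalization log2-transforms, centers and is idempotent", {
  qm <- qm_from_matrix(matrix(c(2, 4, 8, 1, 4, 16), ncol = 2),
                       log2_scale = FALSE)
  norm <- normalize_quant(qm)
  expect_equal(norm$`126`, c(-1, 0, 1))
  expect_equal(norm$`127N`, c(-2, 0, 2))
  # channel medians are zero
  expect_lt(max(abs(apply(as.matrix(norm[c("126", "127N")]), 2,
                          stats::median))), 1e-9)
  # idempotent on an already-centered log2 matrix
  again <- normalize_quant(norm)
  expect_equal(again$`126`, norm$`126`)
  # rank order within channel preserved
  set.seed(51)
  raw <- qm_from_matrix(matrix(2^stats::rnorm(60, 20, 2), ncol = 3),
                        log2_scale = FALSE)
  nm <- normalize_quant(raw)
  expect_equal(order(nm$`126`), order(raw$`126`))
  # zeros become missing rather than -Inf
  with_zero <- qm_from_matrix(matrix(c(0, 4, 8, 2, 4, 8), ncol = 2),
                              log2_scale = FALSE)
  expect_true(is.na(normalize_quant(with_zero)$`126`[1]))
  # mean centering differs from median centering under an outlier
  skew <- qm_from_matrix(matrix(c(2, 4, 2^10, 2, 4, 8), ncol = 2),
                         log2_scale = FALSE)
  med <- normalize_quant(skew, center = "median")
  avg <- normalize_quant(skew, center = "mean")
  expect_false(isTRUE(all.equal(med$`126`, avg$`126`)))
  expect_lt(abs(mean(avg$`126`)), 1e-9)
})

test_that("PRM quantification sums inside a closed RT window and normalizes", {
  psm <- make_psm(1)
  psm$`126` <- 1000
  totals <- c(`126` = 1e6, `127N` = 1e6, `128N` = 1e6, `129N` = 1e6)
  out <- prm_quantify(psm, totals)
  expect_equal(out$abundance[out$channel == "126"], 1e-3)
  # 29 spectra inside the window, the rest excluded
  many <- make_psm(40)
  many$`126` <- 100
  many$rt <- c(seq(31.2, 32.9, length.out = 29), seq(40, 50, length.out = 11))
  out29 <- prm_quantify(many, totals, rt_window = c(31.2, 32.9))
  expect_equal(out29$summed[out29$channel == "126"], 29 * 100)
  # all PSMs outside the window sum to zero
  none <- prm_quantify(many, totals, rt_window = c(10, 11))
  expect_true(all(none$summed == 0))
  expect_error(prm_quantify(psm, c(totals[-1], `126` = 0)), "total")
})

test_that("enrichment overlap share reproduces set arithmetic", {
  out <- enrichment_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(out$n_shared, 2)
  expect_equal(out$n_total, 4)
  expect_equal(out$share_pct, 50)
  counted <- enrichment_overlap(counts = c(n_shared = 216, n_total = 954))
  expect_equal(counted$share_pct, 100 * 216 / 954)
})
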