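# Differential abundance: empirical-Bayes moderated t implemented from the
# closed-form formulas (per-feature residual variances shrunk toward a prior
# estimated by digamma/trigamma moment matching on log s^2), BH q-values,
# plain two-sample t-tests, and glycan-class-level summaries.

# Newton solve of trigamma(y) = x (x > 0); standard starting value 0.5 + 1/x
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matching on `log(s^2)`: with `e = log(s^2) - digamma(d/2) +
#' log(d/2)`, the prior degrees of freedom solve
#' `trigamma(d0/2) = mean((e - mean(e))^2 * n/(n-1) - trigamma(d/2))`
#' and `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. A non-positive
#' right-hand side yields `d0 = Inf` (all features share one variance).
#' Features with zero residual degrees of freedom or zero variance are
#' excluded from the fit.
#'
#' @param s2 Per-feature residual variances.
#' @param df Matching residual degrees of freedom.
#' @return A list with `d0` and `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2) stop("need at least two positive-variance features",
                           call. = FALSE)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  rhs <- mean((e - emean)^2 * n / (n - 1) - trigamma(df / 2))
  if (rhs > 0) {
    d0 <- 2 * .trigamma_inverse(rhs)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated two-group t-statistics
#'
#' For each feature the two group means and pooled residual variance `s_g^2`
#' (with `d_g = n1 + n2 - 2` degrees of freedom) are computed over finite
#' values; the posterior variance shrinks `s_g^2` toward the estimated prior,
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and the moderated statistic
#' `t~ = (mean1 - mean2) / (s~_g sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution on `d0 + d_g` degrees of freedom. p-values are converted to
#' BH q-values. With `d0 = 0` this is the ordinary pooled t-test; as
#' `d0 -> Inf` it approaches the fixed-variance z-like statistic.
#'
#' @param qm A normalized, log2-scale quant matrix ([normalize_quant()]).
#'   Features quantified in fewer than 70% of channels are dropped first (no
#'   imputation).
#' @param design A tibble with columns `channel` and `group`.
#' @param groups Length-2 character: which `group` level is case and which
#'   control; the contrast is case minus control.
#' @param prior Optional fixed prior `list(d0 =, s0_sq =)` overriding
#'   estimation (use `d0 = 0` for the ordinary t limit).
#' @param min_frac Completeness threshold passed to
#'   [filter_feature_completeness()].
#' @return A `glyco_diff` tibble: feature metadata plus `mean_case`,
#'   `mean_control`, `log2fc` (case - control), `ratio` (`2^log2fc`),
#'   `s2`, `df_residual`, `t`, `df_total`, `p`, `q`, `direction` (`"Up"` /
#'   `"Down"`), `zero_variance`. The prior is attached as attribute
#'   `"prior"`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_features = c(intact_N = 50,
#'                                                        desialo_O = 5),
#'                                         outlier_channel = NULL, seed = 3))
#' qm <- quantify_psms(cohort$psm$intact_N)
#' fit <- fit_moderated_t(qm, cohort$design)
#' head(fit)
#' @export
fit_moderated_t <- function(qm, design, groups = c("case", "control"),
                            prior = NULL, min_frac = 0.7) {
  ch <- intersect(.channel_cols(qm), design$channel)
  if (length(unique(design$group[design$channel %in% ch])) < 2) {
    stop("need two groups with quantified channels", call. = FALSE)
  }
  qm <- filter_feature_completeness(qm[, c(setdiff(names(qm), .channel_cols(qm)), ch)],
                                    min_frac = min_frac)
  m <- as.matrix(qm[ch])
  case_ch <- design$channel[design$group == groups[1] & design$channel %in% ch]
  ctrl_ch <- design$channel[design$group == groups[2] & design$channel %in% ch]
  mc <- m[, case_ch, drop = FALSE]
  mk <- m[, ctrl_ch, drop = FALSE]
  n1 <- rowSums(is.finite(mc)); n2 <- rowSums(is.finite(mk))
  keep <- n1 >= 2 & n2 >= 2
  if (!any(keep)) stop("no feature has >= 2 finite values per group", call. = FALSE)
  qm <- qm[keep, ]; mc <- mc[keep, , drop = FALSE]; mk <- mk[keep, , drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]
  m1 <- rowMeans(mc, na.rm = TRUE); m2 <- rowMeans(mk, na.rm = TRUE)
  rss <- rowSums((mc - m1)^2, na.rm = TRUE) + rowSums((mk - m2)^2, na.rm = TRUE)
  dg <- n1 + n2 - 2
  s2 <- rss / dg
  zero_var <- s2 <= .Machine$double.eps
  if (is.null(prior)) prior <- estimate_variance_prior(s2[!zero_var], dg[!zero_var])
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  tstat <- (m1 - m2) / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- if (is.infinite(d0)) rep(Inf, length(dg)) else d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df_total)
  meta <- qm[setdiff(names(qm), .channel_cols(qm))]
  out <- dplyr::bind_cols(meta, tibble::tibble(
    mean_case = m1, mean_control = m2,
    log2fc = m1 - m2, ratio = 2^(m1 - m2),
    s2 = s2, df_residual = dg,
    t = tstat, df_total = df_total, p = p,
    q = bh_qvalues(p),
    direction = ifelse(m1 - m2 > 0, "Up", "Down"),
    zero_variance = zero_var
  ))
  class(out) <- c("glyco_diff", class(out))
  attr(out, "prior") <- prior
  attr(out, "groups") <- groups
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values: `q_(i) = min_(j >= i) p_(j) * m / j`, clipped
#' at 1 (computed via [stats::p.adjust()]). Invariant under permutation of
#' the input; monotone nondecreasing in sorted p order; never below p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order (empty in, empty out).
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.04))
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Plain two-sample t-test
#'
#' Unpaired two-tailed t-test (pooled by default, Welch optionally), used
#' for PRM confirmation and class-level comparisons. Degenerate inputs where
#' both groups have zero variance are flagged rather than erroring: the
#' statistic is 0 (p = 1) when the means agree and infinite (p = 0)
#' otherwise.
#'
#' @param values Numeric vector.
#' @param labels Grouping vector (two levels; the contrast is first minus
#'   second level).
#' @param welch Use the Welch (unequal-variance) form.
#' @return A one-row tibble: `t`, `df`, `p`, `degenerate`.
#' @examples
#' two_sample_t(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
two_sample_t <- function(values, labels, welch = FALSE) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2)
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                          df = length(x) + length(y) - 2,
                          p = if (same) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
}

#' Glycan-class-level abundance summaries
#'
#' Groups intact glycopeptides by [classify_glycan()] class, computes each
#' class's share of total linear reporter intensity per channel (shares sum
#' to 1), and compares shares between groups with a two-sample t-test per
#' class. Classes absent from all features are omitted with a warning.
#'
#' @param qm A raw (linear-scale) quant matrix of intact glycopeptides with
#'   a `composition` column.
#' @param design Channel/group design tibble.
#' @param welch Use Welch t-tests.
#' @return A list with `abundance` (tibble: `channel`, `group`,
#'   `glycan_class`, `fraction`) and `tests` (tibble: `glycan_class`, `t`,
#'   `df`, `p`).
#' @export
summarize_glyco_classes <- function(qm, design, welch = FALSE) {
  stopifnot("composition" %in% names(qm))
  ch <- intersect(.channel_cols(qm), design$channel)
  qm$glycan_class <- classify_glycan(qm$composition)
  absent <- setdiff(glycan_classes(), unique(qm$glycan_class))
  if (length(absent) > 0) {
    warning("glycan class(es) absent from the data: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  long <- qm |>
    dplyr::select("feature_id", "glycan_class", dplyr::all_of(ch)) |>
    tidyr::pivot_longer(dplyr::all_of(ch), names_to = "channel",
                        values_to = "intensity") |>
    dplyr::group_by(.data$channel, .data$glycan_class) |>
    dplyr::summarise(intensity = sum(.data$intensity, na.rm = TRUE),
                     .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$intensity / sum(.data$intensity)) |>
    dplyr::ungroup() |>
    dplyr::left_join(design, by = "channel") |>
    dplyr::select("channel", "group", "glycan_class", "fraction")
  tests <- long |>
    dplyr::group_by(.data$glycan_class) |>
    dplyr::group_modify(function(d, key) {
      two_sample_t(d$fraction, d$group, welch = welch)[c("t", "df", "p")]
    }) |>
    dplyr::ungroup()
  list(abundance = long, tests = tests)
}
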