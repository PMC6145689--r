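# PCA with outlier-sample QC, Euclidean hierarchical clustering, and
# PLS-DA cross-validated ROC for panel evaluation.

# samples x features matrix restricted to complete features
.sample_matrix <- function(qm, channels = NULL) {
  ch <- .channel_cols(qm)
  if (!is.null(channels)) ch <- intersect(ch, channels)
  m <- as.matrix(qm[ch])
  rownames(m) <- qm$feature_id
  complete <- rowSums(!is.finite(m)) == 0
  t(m[complete, , drop = FALSE])
}

#' Principal component analysis of samples
#'
#' Singular value decomposition of the column-centered samples x features
#' table (features with any missing channel are excluded; no imputation).
#' Unit-variance scaling is off by default: reporter log2 intensities are
#' already on one common scale.
#'
#' @param qm A log2-scale quant matrix.
#' @param design Optional design tibble (adds a `group` column to scores).
#' @param scale Scale features to unit variance.
#' @param k Number of components to keep (capped by the data rank).
#' @return A `glyco_pca` object: list with `scores` (tibble: `channel`,
#'   `group`, `PC1`, ...), `loadings`, `explained` (variance fractions,
#'   nonincreasing) and the `prcomp` fit.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_features = c(intact_N = 40,
#'                                                        desialo_O = 5),
#'                                         seed = 2))
#' qm <- quantify_psms(cohort$psm$intact_N, normalize = FALSE) |>
#'   normalize_quant()
#' pca <- pca_samples(qm, cohort$design)
#' pca$explained
#' @export
pca_samples <- function(qm, design = NULL, scale = FALSE, k = 5) {
  x <- .sample_matrix(qm, design$channel)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 samples and >= 2 features",
                                       call. = FALSE)
  constant <- apply(x, 2, stats::sd) == 0
  if (scale) x <- x[, !constant, drop = FALSE]
  if (all(apply(x, 2, stats::sd) == 0)) stop("rank-0 input", call. = FALSE)
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  k <- min(k, ncol(fit$x))
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(channel = rownames(x)), scores)
  if (!is.null(design)) {
    scores <- dplyr::left_join(scores, design, by = "channel") |>
      dplyr::relocate("channel", "group")
  }
  structure(list(scores = scores,
                 loadings = fit$rotation[, seq_len(k), drop = FALSE],
                 explained = expl[seq_len(k)], fit = fit),
            class = "glyco_pca")
}

#' Flag outlier samples in PC space
#'
#' A sample is flagged when its Euclidean distance from the centroid in the
#' PC1-PC2 plane exceeds `k_mad` times the median distance of all samples.
#' Run this on the log2 matrix before per-channel centering: a degraded
#' channel typically shows a global intensity shift which per-channel
#' normalization would absorb.
#'
#' @param pca A [pca_samples()] result (>= 4 samples).
#' @param k_mad Multiplier on the median distance (default 3).
#' @return A tibble with `channel`, `dist` and logical `flagged`.
#' @export
detect_outlier_samples <- function(pca, k_mad = 3) {
  stopifnot(inherits(pca, "glyco_pca"))
  sc <- as.matrix(pca$scores[, c("PC1", "PC2")])
  if (nrow(sc) < 4) stop("need >= 4 samples for outlier detection", call. = FALSE)
  centroid <- colMeans(sc)
  d <- sqrt(rowSums(sweep(sc, 2, centroid)^2))
  tibble::tibble(channel = pca$scores$channel, dist = d,
                 flagged = d > k_mad * stats::median(d))
}

#' Hierarchical clustering of features
#'
#' Agglomerative clustering of feature rows on Euclidean distance (average
#' linkage by default), as used for heat-map ordering; cutting the tree at
#' two clusters separates over- and under-represented feature blocks on
#' signed (centered log2) data.
#'
#' @param qm A quant matrix (features in rows).
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param k Number of flat clusters to cut.
#' @return A list with `hclust`, `order` (feature ids in dendrogram order)
#'   and `clusters` (tibble: `feature_id`, `cluster`).
#' @export
hierarchical_cluster <- function(qm, metric = "euclidean",
                                 linkage = "average", k = 2) {
  ch <- .channel_cols(qm)
  m <- as.matrix(qm[ch])
  rownames(m) <- qm$feature_id
  m <- m[rowSums(!is.finite(m)) == 0, , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  cl <- stats::cutree(hc, k = k)
  list(hclust = hc, order = rownames(m)[hc$order],
       clusters = tibble::tibble(feature_id = rownames(m),
                                 cluster = unname(cl)))
}

#' Mann-Whitney AUC of scores against binary labels
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half; equivalently the normalized rank-sum statistic.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric vector.
#' @param labels Logical or two-level vector (`TRUE`/first level = positive).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.3, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, labels) {
  if (!is.logical(labels)) {
    labels <- as.factor(labels)
    stopifnot(nlevels(labels) == 2)
    labels <- labels == levels(labels)[1]
  }
  pos <- scores[labels]; neg <- scores[!labels]
  stopifnot(length(pos) > 0, length(neg) > 0)
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

#' PLS-DA cross-validated ROC over nested panel sizes
#'
#' Ranks features (by absolute moderated t by default, or by PLS-DA VIP),
#' and for each requested panel size fits a two-component PLS-DA under
#' leave-one-out cross-validation; the AUC is computed from the held-out
#' predicted class scores by the rank-sum formula ([roc_auc()]).
#'
#' @param qm A normalized quant matrix.
#' @param design Design tibble (binary groups, >= 2 samples per class).
#' @param panel_sizes Integer vector of panel sizes (each <= number of
#'   rankable features).
#' @param ranking `"moderated_t"` (default) or `"vip"`; alternatively a
#'   character vector of feature ids already in rank order.
#' @param groups Case/control levels as in [fit_moderated_t()].
#' @param ncomp PLS components (default 2).
#' @return A `glyco_roc` tibble: `panel_size`, `auc`, and a `scores`
#'   list-column of per-sample held-out score tibbles.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(
#'   cohort_config(effects = load_table1_fixture()[1:10, ],
#'                 n_features = c(intact_N = 50, desialo_O = 5),
#'                 outlier_channel = NULL, seed = 4))
#' qm <- quantify_psms(cohort$psm$intact_N)
#' plsda_roc(qm, cohort$design, panel_sizes = c(5, 10))
#' }
#' @export
plsda_roc <- function(qm, design, panel_sizes, ranking = "moderated_t",
                      groups = c("case", "control"), ncomp = 2) {
  design <- design[design$channel %in% .channel_cols(qm), ]
  if (min(table(design$group)) < 2) {
    stop("each class needs >= 2 samples", call. = FALSE)
  }
  x <- .sample_matrix(qm, design$channel)
  x <- x[design$channel, , drop = FALSE]
  if (length(ranking) == 1 && ranking %in% c("moderated_t", "vip")) {
    ranked <- if (ranking == "moderated_t") {
      fit <- fit_moderated_t(qm, design, groups = groups)
      fit$feature_id[order(-abs(fit$t))]
    } else {
      full <- mixOmics::plsda(x, factor(design$group), ncomp = ncomp)
      v <- mixOmics::vip(full)
      rownames(v)[order(-v[, ncomp])]
    }
  } else {
    ranked <- ranking
  }
  ranked <- ranked[ranked %in% colnames(x)]
  stopifnot(all(panel_sizes <= length(ranked)))
  y <- factor(design$group, levels = groups)
  res <- purrr::map_dfr(panel_sizes, function(sz) {
    feats <- ranked[seq_len(sz)]
    held <- vapply(seq_len(nrow(x)), function(i) {
      xi <- x[-i, feats, drop = FALSE]
      keep <- apply(xi, 2, stats::sd) > 0
      fit <- mixOmics::plsda(xi[, keep, drop = FALSE], y[-i],
                             ncomp = min(ncomp, sum(keep)))
      pr <- stats::predict(fit, x[i, feats[keep], drop = FALSE])
      pr$predict[1, groups[1], dim(pr$predict)[3]]
    }, numeric(1))
    tibble::tibble(panel_size = sz,
                   auc = roc_auc(held, y == groups[1]),
                   scores = list(tibble::tibble(channel = design$channel,
                                                group = design$group,
                                                score = held)))
  })
  class(res) <- c("glyco_roc", class(res))
  res
}
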