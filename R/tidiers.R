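# broom-style tidy()/glance() methods and ggplot2 visualisations.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a moderated-t differential result
#'
#' @param x A `glyco_diff` object.
#' @param ... Unused.
#' @return `tidy()`: the per-feature results as a plain tibble. `glance()`:
#'   a one-row summary with the number of features, the empirical-Bayes
#'   prior (`d0`, `s0_sq`) and the count of q <= 0.25 features.
#' @method tidy glyco_diff
#' @export
tidy.glyco_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "glyco_diff")
  tibble::as_tibble(out)
}

#' @rdname tidy.glyco_diff
#' @method glance glyco_diff
#' @export
glance.glyco_diff <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble::tibble(n_features = nrow(x), d0 = prior$d0, s0_sq = prior$s0_sq,
                 n_q25 = sum(x$q <= 0.25))
}

#' @rdname tidy.glyco_diff
#' @method tidy glyco_roc
#' @export
tidy.glyco_roc <- function(x, ...) {
  tidyr::unnest(tibble::as_tibble(x)[c("panel_size", "auc", "scores")],
                "scores")
}

#' @rdname tidy.glyco_diff
#' @method glance glyco_roc
#' @export
glance.glyco_roc <- function(x, ...) {
  tibble::tibble(n_panels = nrow(x), min_auc = min(x$auc),
                 max_auc = max(x$auc))
}

#' @rdname tidy.glyco_diff
#' @method tidy glyco_pca
#' @export
tidy.glyco_pca <- function(x, ...) x$scores

#' @rdname tidy.glyco_diff
#' @method glance glyco_pca
#' @export
glance.glyco_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$explained),
                 pc1_var = x$explained[1],
                 pc2_var = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' Plot PCA sample scores
#'
#' @param object A `glyco_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot glyco_pca
#' @export
autoplot.glyco_pca <- function(object, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(size = 3, ggplot2::aes(
      colour = if ("group" %in% names(sc)) .data$group else NULL)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel),
                       vjust = -1, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
  p
}

#' Plot cross-validated ROC AUC against panel size
#'
#' @param object A `glyco_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot glyco_roc
#' @export
autoplot.glyco_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$panel_size), .data$auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "panel size (glycopeptides)",
                  y = "cross-validated AUC") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential result
#'
#' @param object A `glyco_diff` object.
#' @param q_max Highlighting threshold.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot glyco_diff
#' @export
autoplot.glyco_diff <- function(object, q_max = 0.25, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                  colour = .data$q <= q_max)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 name = paste0("q ≤ ", q_max)) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Heat map of a quant matrix with dendrogram ordering
#'
#' @param qm A normalized quant matrix.
#' @param design Optional design (orders channels by group).
#' @param cluster A [hierarchical_cluster()] result (computed if `NULL`).
#' @return A ggplot tile map with features in dendrogram order.
#' @export
plot_heatmap <- function(qm, design = NULL, cluster = NULL) {
  if (is.null(cluster)) cluster <- hierarchical_cluster(qm)
  ch <- .channel_cols(qm)
  long <- qm |>
    dplyr::select("feature_id", dplyr::all_of(ch)) |>
    tidyr::pivot_longer(dplyr::all_of(ch), names_to = "channel",
                        values_to = "log2") |>
    dplyr::mutate(feature_id = factor(.data$feature_id,
                                      levels = cluster$order))
  if (!is.null(design)) {
    long$channel <- factor(long$channel,
                           levels = design$channel[order(design$group)])
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$channel, .data$feature_id,
                                     fill = .data$log2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2")
}
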