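# End-to-end orchestration: filters, aggregation, outlier QC, normalization,
# differential statistics, panel selection and ROC evaluation.

#' Run the full glycoproteomics analysis pipeline
#'
#' Orchestrates the analysis end to end on PSM tables of the four peptide
#' classes: (1) PIF/PEP-2D and target-decoy FDR filtering per class,
#' (2) aggregation of redundant PSMs to feature-level summed reporter
#' intensities, (3) log2 transform and PCA-based outlier-channel QC on the
#' intact-glycopeptide matrix (before per-channel centering, which would
#' absorb a global channel shift), (4) per-channel median (or mean)
#' normalization on the surviving channels, (5) moderated-t differential
#' abundance for the intact, de-N and non-modified classes, (6) de-N site
#' corroboration, whitelist and q / fold-change gating into a panel with
#' protein-level cross-references, (7) PLS-DA leave-one-out ROC of ranked
#' sub-panels, and (8) glycan-class-level abundance summaries. The run is
#' deterministic for fixed inputs.
#'
#' @param psm Named list of PSM tibbles: `intact_N`, and optionally
#'   `desialo_O`, `de_N`, `non_modified` (as produced by
#'   [simulate_cohort()]`$psm` or [read_psm_table()]).
#' @param design Tibble with `channel` and `group` columns.
#' @param thresholds Named list overriding any of `pif_min` (0.75),
#'   `pep2d_max` (0.001), `peptide_fdr_max` (0), `q_max` (0.25), `fc_up`
#'   (1.3), `fc_down` (0.77), `min_frac` (0.7), `k_mad` (3).
#' @param center Channel centering statistic (`"median"` or `"mean"`).
#' @param outliers `"auto"` (PCA QC), `"none"`, or a character vector of
#'   channels to exclude manually.
#' @param panel_sizes Panel sizes for the ROC evaluation.
#' @param whitelist Glycoform whitelist ([default_glycoform_whitelist()]).
#' @param protein_seqs Optional protein sequences for protein-coordinate
#'   site matching ([corroborate_sites()]).
#' @return A `glyco_pipeline` list: `design` (channels retained), `removed_channels`,
#'   `quant` (normalized matrices per class), `raw` (summed matrices),
#'   `pca`, `outliers`, `diff` (per class), `class_summary`,
#'   `corroboration`, `panel`, `roc`, `thresholds`, `manifest`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(
#'   effects = load_table1_fixture()[1:20, ],
#'   n_features = c(intact_N = 100, desialo_O = 20), seed = 11))
#' res <- run_pipeline(cohort$psm, cohort$design, panel_sizes = c(5, 10))
#' res$manifest
#' }
#' @export
run_pipeline <- function(psm, design,
                         thresholds = list(),
                         center = "median",
                         outliers = "auto",
                         panel_sizes = c(3, 5, 10, 20, 28, 56),
                         whitelist = default_glycoform_whitelist(),
                         protein_seqs = NULL) {
  stopifnot("intact_N" %in% names(psm))
  th <- utils::modifyList(list(pif_min = 0.75, pep2d_max = 0.001,
                               peptide_fdr_max = 0, q_max = 0.25,
                               fc_up = 1.3, fc_down = 0.77,
                               min_frac = 0.7, k_mad = 3), thresholds)
  manifest <- list()
  note <- function(stage, n) manifest[[stage]] <<- n

  raw <- purrr::imap(psm, function(tab, class) {
    out <- tryCatch(
      quantify_psms(tab, pif_min = th$pif_min, pep2d_max = th$pep2d_max,
                    peptide_fdr_max = th$peptide_fdr_max, normalize = FALSE),
      error = function(e) stop("stage quantify [", class, "]: ",
                               conditionMessage(e), call. = FALSE))
    note(paste0("quantify_", class), nrow(out))
    out
  })

  # outlier QC on the uncentered log2 intact matrix
  pre_log2 <- raw$intact_N
  chn <- .channel_cols(pre_log2)
  m <- as.matrix(pre_log2[chn]); m[m <= 0] <- NA
  pre_log2[chn] <- tibble::as_tibble(base::log2(m))
  attr(pre_log2, "log2_scale") <- TRUE
  pca_qc <- pca_samples(pre_log2, design)
  if (identical(outliers, "auto")) {
    flags <- detect_outlier_samples(pca_qc, k_mad = th$k_mad)
    removed <- flags$channel[flags$flagged]
  } else if (identical(outliers, "none")) {
    flags <- NULL
    removed <- character(0)
  } else {
    flags <- NULL
    removed <- outliers
  }
  design_used <- design[!design$channel %in% removed, ]
  note("outlier_channels_removed", length(removed))

  keep_cols <- function(qm) {
    qm[, !names(qm) %in% removed]
  }
  quant <- purrr::map(raw, function(r) {
    normalize_quant(keep_cols(r), center = center)
  })

  run_diff <- function(class) {
    if (!class %in% names(quant)) return(NULL)
    tryCatch(
      fit_moderated_t(quant[[class]], design_used, min_frac = th$min_frac),
      error = function(e) stop("stage diff [", class, "]: ",
                               conditionMessage(e), call. = FALSE))
  }
  diff <- list(intact_N = run_diff("intact_N"),
               de_N = run_diff("de_N"),
               non_modified = run_diff("non_modified"))
  note("diff_intact_features", nrow(diff$intact_N))

  class_summary <- summarize_glyco_classes(keep_cols(raw$intact_N), design_used)

  # site corroboration is identification-level evidence: PEP-2D and FDR
  # filtered, but not PIF-gated (PIF protects quantification only)
  corr <- if ("de_N" %in% names(psm)) {
    den_id <- psm$de_N |>
      filter_psms(pif_min = NULL, pep2d_max = th$pep2d_max) |>
      fdr_filter(peptide_fdr_max = th$peptide_fdr_max) |>
      dplyr::distinct(.data$protein, .data$peptide)
    if (!is.null(diff$de_N)) {
      den_id <- dplyr::left_join(
        den_id, diff$de_N[c("protein", "peptide", "ratio")],
        by = c("protein", "peptide"))
    }
    corroborate_sites(diff$intact_N, den_id, protein_seqs = protein_seqs)
  } else {
    dplyr::mutate(diff$intact_N, corroborated = FALSE,
                  den_peptide = NA_character_)
  }
  panel <- select_panel(diff$intact_N, corr, whitelist = whitelist,
                        q_max = th$q_max, fc_up = th$fc_up,
                        fc_down = th$fc_down)
  if (!is.null(diff$non_modified)) {
    panel <- crossref_protein_level(panel, diff$non_modified,
                                    fc_up = th$fc_up, fc_down = th$fc_down)
  }
  note("panel_entries", nrow(panel))

  sizes <- panel_sizes[panel_sizes <= nrow(diff$intact_N)]
  roc <- plsda_roc(quant$intact_N, design_used, panel_sizes = sizes)
  note("roc_panels", nrow(roc))

  structure(list(
    design = design_used, removed_channels = removed,
    raw = raw, quant = quant, pca = pca_qc, outliers = flags,
    diff = diff, class_summary = class_summary,
    corroboration = corr, panel = panel, roc = roc,
    thresholds = th,
    manifest = tibble::tibble(stage = names(manifest),
                              n = unlist(manifest))
  ), class = "glyco_pipeline")
}

#' @export
print.glyco_pipeline <- function(x, ...) {
  cat("Glycoproteomics pipeline run\n")
  cat("  channels: ", nrow(x$design), " (removed: ",
      if (length(x$removed_channels) == 0) "none" else
        paste(x$removed_channels, collapse = ", "), ")\n", sep = "")
  cat("  intact features tested:", nrow(x$diff$intact_N), "\n")
  cat("  panel entries:", nrow(x$panel), "\n")
  cat("  ROC: ", paste(sprintf("%d->%.2f", x$roc$panel_size, x$roc$auc),
                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write pipeline results as tab-separated tables
#'
#' @param x A `glyco_pipeline` result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_pipeline_results <- function(x, dir) {
  stopifnot(inherits(x, "glyco_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    diff = file.path(dir, "diff_intact_N.tsv"),
    panel = file.path(dir, "panel.tsv"),
    roc = file.path(dir, "roc.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  readr::write_tsv(tibble::as_tibble(x$diff$intact_N), paths["diff"],
                   progress = FALSE)
  readr::write_tsv(dplyr::select(x$panel, !dplyr::any_of("scores")),
                   paths["panel"], progress = FALSE)
  readr::write_tsv(dplyr::select(x$roc, "panel_size", "auc"), paths["roc"],
                   progress = FALSE)
  readr::write_tsv(x$manifest, paths["manifest"], progress = FALSE)
  invisible(paths)
}
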