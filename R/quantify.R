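# PSM ingestion, identification-quality filtering, reporter-ion aggregation
# and normalization.

.psm_required_cols <- c("peptide", "mods", "composition", "charge", "score",
                        "pep2d", "pif", "decoy", "rt")

# reporter-intensity columns of a PSM table / quant matrix
.channel_cols <- function(df) intersect(.tmt10_channels, names(df))

#' Read / write a tab-separated PSM table
#'
#' The tabular PSM dialect (version 1) has one row per peptide-spectrum
#' match with columns `spectrum_id`, `peptide`, `mods`, `composition`
#' (canonical `Name(count)` string, empty for non-glycosylated classes),
#' `charge`, `score`, `pep2d`, `pif`, `decoy`, `rt`, plus one reporter
#' intensity column per TMT channel (named `126`, `127N`, ...). Compositions
#' are validated through the glycan parser on read.
#'
#' @param path File path.
#' @param psm A PSM tibble (for writing).
#' @return `read_psm_table()`: a tibble of PSM records.
#' @examples
#' \dontrun{
#' psm <- read_psm_table("psms.tsv")
#' }
#' @export
read_psm_table <- function(path) {
  psm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           composition = readr::col_character(),
                           peptide = readr::col_character(),
                           mods = readr::col_character()
                         ))
  missing <- setdiff(.psm_required_cols, names(psm))
  if (length(missing) > 0) {
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(.channel_cols(psm)) < 2) {
    stop("PSM table needs at least two reporter-intensity channel columns",
         call. = FALSE)
  }
  has_comp <- which(!is.na(psm$composition) & nzchar(psm$composition))
  for (i in has_comp) {
    parsed <- tryCatch(parse_composition(psm$composition[i]), error = identity)
    if (inherits(parsed, "error")) {
      stop("row ", i, ": ", conditionMessage(parsed), call. = FALSE)
    }
  }
  psm
}

#' @rdname read_psm_table
#' @export
write_psm_table <- function(psm, path) {
  readr::write_tsv(psm, path, progress = FALSE)
  invisible(path)
}

#' Filter PSMs on precursor purity and identification confidence
#'
#' Keeps PSMs with precursor ion fraction strictly above `pif_min` (reporter
#' ratios of co-isolated precursors are compressed toward 1, so low-PIF
#' spectra are unquantifiable) and posterior error probability strictly below
#' `pep2d_max`. Records with `NA` `pep2d` (the non-modified peptide class,
#' which is not scored by the glycopeptide search) are exempt from the PEP
#' gate.
#'
#' @param psm A PSM tibble.
#' @param pif_min,pep2d_max Thresholds in (0, 1); boundary values are
#'   excluded. Either can be `NULL` to skip that gate: the PIF gate guards
#'   quantification only, so identification-level evidence (e.g. the de-N
#'   glycosite list used for corroboration) is filtered with
#'   `pif_min = NULL`.
#' @return The filtered tibble.
#' @examples
#' psm <- tibble::tibble(pif = c(0.8, 0.75, 0.6), pep2d = 1e-4)
#' filter_psms(psm)
#' @export
filter_psms <- function(psm, pif_min = 0.75, pep2d_max = 0.001) {
  if (!is.null(pif_min)) {
    stopifnot(pif_min > 0, pif_min < 1)
    psm <- dplyr::filter(psm, .data$pif > pif_min)
  }
  if (!is.null(pep2d_max)) {
    stopifnot(pep2d_max > 0, pep2d_max < 1)
    psm <- dplyr::filter(psm, is.na(.data$pep2d) | .data$pep2d < pep2d_max)
  }
  psm
}

#' Target-decoy FDR filtering
#'
#' Sorts PSMs by search score (descending; on ties decoys first, which is
#' conservative), computes the running FDR `#decoys / #targets` down the
#' list, keeps the deepest prefix whose running FDR stays within
#' `peptide_fdr_max`, and returns its target PSMs. At the default of 0 this
#' keeps all targets that outscore the best decoy.
#'
#' @param psm A PSM tibble with `score` and logical `decoy` columns.
#' @param peptide_fdr_max Maximum running FDR (default 0).
#' @return Target PSMs passing the cutoff (possibly empty).
#' @examples
#' psm <- tibble::tibble(score = c(0.9, 0.8, 0.7, 0.6),
#'                       decoy = c(FALSE, FALSE, TRUE, FALSE))
#' fdr_filter(psm)
#' @export
fdr_filter <- function(psm, peptide_fdr_max = 0) {
  if (nrow(psm) == 0 || !any(!psm$decoy)) return(psm[!psm$decoy, ])
  ord <- order(-psm$score, !psm$decoy)
  sorted <- psm[ord, ]
  n_decoy <- cumsum(sorted$decoy)
  n_target <- cumsum(!sorted$decoy)
  fdr <- n_decoy / pmax(n_target, 1)
  ok <- which(fdr <= peptide_fdr_max & n_target > 0)
  if (length(ok) == 0) return(sorted[0, ])
  keep <- sorted[seq_len(max(ok)), ]
  keep[!keep$decoy, ]
}

#' Aggregate PSMs to feature-level reporter intensities
#'
#' Features are keyed by peptide + modifications + glycan composition
#' (charge states merged); reporter intensities of redundant PSMs are summed
#' channel-wise. Aggregation is order-independent.
#'
#' @param psm A filtered PSM tibble.
#' @return A raw quant matrix: one row per feature with `feature_id`,
#'   `peptide`, `mods`, `composition`, `protein` (if present), `n_psm` and
#'   the summed channel columns.
#' @export
aggregate_to_features <- function(psm) {
  ch <- .channel_cols(psm)
  keys <- intersect(c("peptide", "mods", "composition", "protein"), names(psm))
  out <- psm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_psm = dplyr::n(),
                     dplyr::across(dplyr::all_of(ch), sum),
                     .groups = "drop") |>
    dplyr::arrange(.data$peptide)
  comp_key <- if ("composition" %in% names(out))
    tidyr::replace_na(out$composition, "") else ""
  out$feature_id <- paste(out$peptide, comp_key, sep = "|")
  dplyr::relocate(out, "feature_id")
}

#' Log2-transform and per-channel centering of a quant matrix
#'
#' `normalize_quant()` log2-transforms raw summed intensities (zeros become
#' missing) and centers each channel at zero by its median (default) or mean.
#' Centering is idempotent and preserves within-channel rank order; after
#' centering every channel's median (or mean) over finite values is 0.
#' An already log2-scale matrix (attribute set by a previous call, or
#' `log2 = FALSE`) is centered only.
#'
#' @param qm A quant matrix (from [aggregate_to_features()]).
#' @param center `"median"` or `"mean"`. Cohort analyses here use median
#'   centering by default; mean centering is retained as an option because
#'   both appear in practice for TMT reporter normalization.
#' @param log2 Apply the log2 transform first. Default: yes unless the
#'   matrix is already marked log2-scale.
#' @return The normalized matrix (attribute `log2_scale` set).
#' @examples
#' qm <- tibble::tibble(feature_id = c("a", "b", "c"),
#'                      `126` = c(2, 4, 8), `127N` = c(1, 2, 4))
#' normalize_quant(qm)
#' @export
normalize_quant <- function(qm, center = c("median", "mean"), log2 = NULL) {
  center <- match.arg(center)
  ch <- .channel_cols(qm)
  if (length(ch) == 0) stop("no channel columns found", call. = FALSE)
  do_log <- log2 %||% !isTRUE(attr(qm, "log2_scale"))
  m <- as.matrix(qm[ch])
  if (do_log) {
    m[m <= 0] <- NA  # zero reporter intensity is missing, not log of zero
    m <- base::log2(m)
  }
  centers <- apply(m, 2, function(x) {
    if (all(is.na(x))) stop("channel with no finite values", call. = FALSE)
    if (center == "median") stats::median(x, na.rm = TRUE)
    else mean(x, na.rm = TRUE)
  })
  m <- sweep(m, 2, centers)
  qm[ch] <- tibble::as_tibble(m)
  attr(qm, "log2_scale") <- TRUE
  attr(qm, "center") <- center
  qm
}

#' @rdname normalize_quant
#' @param min_frac Minimum fraction of channels with finite values a feature
#'   needs to enter differential statistics (no imputation is performed).
#' @export
filter_feature_completeness <- function(qm, min_frac = 0.7) {
  ch <- .channel_cols(qm)
  frac <- rowMeans(is.finite(as.matrix(qm[ch])))
  out <- qm[frac >= min_frac, ]
  attr(out, "log2_scale") <- attr(qm, "log2_scale")
  out
}

#' PRM-style normalized quantification of one glycopeptide
#'
#' Sums the reporter intensities of the glycopeptide's PSMs inside a closed
#' retention-time window and normalizes each channel by that channel's total
#' reporter intensity over the whole run.
#'
#' @param psm PSM tibble for one glycopeptide (targeted acquisition).
#' @param channel_totals Named numeric vector of per-channel total reporter
#'   intensity (> 0), names matching the channel columns.
#' @param rt_window Optional numeric length-2 closed retention-time window in
#'   minutes; PSMs outside are excluded.
#' @return A tibble with `channel`, `summed`, `total` and `abundance`
#'   (= summed / total).
#' @export
prm_quantify <- function(psm, channel_totals, rt_window = NULL) {
  ch <- .channel_cols(psm)
  stopifnot(all(ch %in% names(channel_totals)))
  if (any(channel_totals[ch] <= 0)) {
    stop("zero or negative channel total", call. = FALSE)
  }
  if (!is.null(rt_window)) {
    stopifnot(length(rt_window) == 2)
    psm <- dplyr::filter(psm, .data$rt >= rt_window[1], .data$rt <= rt_window[2])
  }
  summed <- colSums(as.matrix(psm[ch]))
  tibble::tibble(channel = ch, summed = as.numeric(summed),
                 total = as.numeric(channel_totals[ch]),
                 abundance = as.numeric(summed / channel_totals[ch]))
}

#' Quantify PSM tables end to end
#'
#' Convenience chain: PIF/PEP filtering, target-decoy FDR filtering,
#' feature aggregation, log2 transform and per-channel centering.
#'
#' @param psm A PSM tibble.
#' @inheritParams filter_psms
#' @inheritParams fdr_filter
#' @inheritParams normalize_quant
#' @param normalize Apply [normalize_quant()] (set `FALSE` to obtain the raw
#'   summed matrix).
#' @return A quant matrix tibble.
#' @export
quantify_psms <- function(psm, pif_min = 0.75, pep2d_max = 0.001,
                          peptide_fdr_max = 0, center = "median",
                          normalize = TRUE) {
  qm <- psm |>
    filter_psms(pif_min = pif_min, pep2d_max = pep2d_max) |>
    fdr_filter(peptide_fdr_max = peptide_fdr_max) |>
    aggregate_to_features()
  if (normalize) normalize_quant(qm, center = center) else qm
}
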