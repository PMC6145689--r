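# The panel-selection cascade: corroborate intact glycopeptide sites against
# de-N-glycosylated evidence, whitelist glycoforms, apply q and fold-change
# gates, and annotate with protein-level (non-modified peptide) behaviour.

#' Corroborate intact glycosites with de-N-glycosylated peptide evidence
#'
#' An intact glycopeptide is corroborated when some de-N-glycosylated
#' peptide maps to the same protein and to an overlapping sequon position.
#' De-N peptides are first validated: only deamidation marks (`(de)`)
#' sitting on a sequon Asn (N-X-S/T/C, X != P) count, mirroring the manual
#' sequon filter applied to PNGase F data. When protein sequences are
#' supplied, sites are compared in protein coordinates (peptide located by
#' exact substring match); otherwise matching falls back to identical
#' peptide strings with the deamidated position on a sequon of the intact
#' peptide.
#'
#' @param intact A tibble of intact glycopeptide features with `feature_id`,
#'   `protein`, `peptide`.
#' @param den A tibble of de-N evidence with `protein` and `peptide` (the
#'   `(de)`-annotated sequence); an optional `ratio` column is carried
#'   through as `den_ratio`.
#' @param protein_seqs Optional named character vector of protein sequences
#'   (names = protein accessions) enabling protein-coordinate matching.
#' @return `intact` with added `corroborated` (logical), `den_peptide` (the
#'   first matching de-N peptide or `NA`) and `den_ratio` (if available).
#' @export
corroborate_sites <- function(intact, den, protein_seqs = NULL) {
  stopifnot(all(c("feature_id", "protein", "peptide") %in% names(intact)),
            all(c("protein", "peptide") %in% names(den)))
  den <- dplyr::distinct(den, .data$protein, .data$peptide,
                         .keep_all = TRUE)
  den$stripped <- strip_deamidation(den$peptide)
  depos <- deamidated_positions(den$peptide)
  # keep only deamidation marks sitting on a sequon of the stripped sequence
  den$valid_sites <- purrr::map2(den$stripped, depos, function(s, pos) {
    intersect(pos, .sequon_positions(s))
  })
  den <- den[lengths(den$valid_sites) > 0, ]

  locate <- function(protein, pep) {
    seqs <- protein_seqs[[protein]]
    if (is.null(seqs)) return(NA_integer_)
    at <- regexpr(pep, seqs, fixed = TRUE)
    if (at == -1) NA_integer_ else as.integer(at)
  }

  match_one <- function(protein, peptide) {
    cand <- den[den$protein == protein, ]
    if (nrow(cand) == 0) return(NA_character_)
    intact_sequons <- .sequon_positions(peptide)
    if (length(intact_sequons) == 0) return(NA_character_)
    if (!is.null(protein_seqs) && !is.null(protein_seqs[[protein]])) {
      off_i <- locate(protein, peptide)
      if (!is.na(off_i)) {
        sites_i <- off_i - 1L + intact_sequons
        for (j in seq_len(nrow(cand))) {
          off_d <- locate(protein, cand$stripped[j])
          if (is.na(off_d)) next
          sites_d <- off_d - 1L + cand$valid_sites[[j]]
          if (length(intersect(sites_i, sites_d)) > 0) return(cand$peptide[j])
        }
        return(NA_character_)
      }
    }
    hit <- which(cand$stripped == peptide &
                   vapply(cand$valid_sites,
                          function(s) length(intersect(s, intact_sequons)) > 0,
                          logical(1)))
    if (length(hit) > 0) cand$peptide[hit[1]] else NA_character_
  }

  matched <- purrr::map2_chr(intact$protein, intact$peptide, match_one)
  out <- intact
  out$den_peptide <- matched
  out$corroborated <- !is.na(matched)
  if ("ratio" %in% names(den)) {
    lut <- stats::setNames(den$ratio, paste(den$protein, den$peptide))
    out$den_ratio <- unname(lut[paste(out$protein, matched)])
  }
  out
}

#' Select the differential intact-glycopeptide panel
#'
#' Applies the four selection gates, an intersection of independent
#' predicates (order-independent): moderated-test `q <= q_max` (inclusive,
#' so borderline entries printed at the threshold pass), fold change
#' strictly outside `[fc_down, fc_up]`, de-N site corroboration, and
#' composition membership in the serum-glycoform whitelist. Every emitted
#' entry is re-checked against these invariants.
#'
#' @param diff A `glyco_diff` tibble for intact glycopeptides (needs
#'   `feature_id`, `protein`, `peptide`, `composition`, `q`, `ratio`).
#' @param corroboration Output of [corroborate_sites()] (or `diff` already
#'   carrying `corroborated` / `den_peptide` columns).
#' @param whitelist Character vector of allowed compositions
#'   ([default_glycoform_whitelist()] by default).
#' @param q_max Inclusive q-value gate (default 0.25).
#' @param fc_up,fc_down Strict ratio gates (default > 1.3 or < 0.77).
#' @return A tibble of panel entries with `direction` (`"Up"`/`"Down"`),
#'   sorted by protein then ratio.
#' @export
select_panel <- function(diff, corroboration = NULL,
                         whitelist = default_glycoform_whitelist(),
                         q_max = 0.25, fc_up = 1.3, fc_down = 0.77) {
  stopifnot(length(whitelist) > 0)
  tab <- if (is.null(corroboration)) diff else
    dplyr::left_join(
      diff,
      corroboration[c("feature_id", "corroborated", "den_peptide",
                      intersect("den_ratio", names(corroboration)))],
      by = "feature_id")
  if (!"corroborated" %in% names(tab)) {
    stop("no corroboration information available", call. = FALSE)
  }
  wl <- format_composition(whitelist)
  tab$composition <- format_composition(tab$composition)
  panel <- dplyr::filter(
    tab,
    .data$q <= q_max,
    .data$ratio > fc_up | .data$ratio < fc_down,
    !is.na(.data$corroborated) & .data$corroborated,
    .data$composition %in% wl
  )
  panel$direction <- ifelse(panel$ratio > 1, "Up", "Down")
  # re-assert the entry invariants
  stopifnot(all(panel$q <= q_max),
            all(panel$ratio > fc_up | panel$ratio < fc_down),
            all(panel$corroborated),
            all(panel$composition %in% wl),
            all(panel$ratio > 0))
  dplyr::arrange(panel, .data$protein, dplyr::desc(.data$ratio))
}

#' Annotate a panel with protein-level behaviour
#'
#' Cross-references each panel entry against the differential results of the
#' non-modified peptide fraction of the same protein: the number of
#' non-modified peptides, their average ratio, and a `glyco_specific` flag
#' set when the glycopeptide's regulation is not explained by protein-level
#' behaviour (protein average ratio inside `[fc_down, fc_up]`, or changing in
#' the opposite direction). Proteins absent from the non-modified data are
#' annotated `protein_evidence = "none"`.
#'
#' @param panel A [select_panel()] result.
#' @param nonmod_diff A `glyco_diff` tibble for non-modified peptides (needs
#'   `protein` and `ratio`).
#' @param fc_up,fc_down The unaltered band for protein-level ratios.
#' @return The panel with `n_nonmod`, `nonmod_avg_ratio`,
#'   `protein_evidence` (`"quantified"`/`"none"`) and `glyco_specific`.
#' @export
crossref_protein_level <- function(panel, nonmod_diff,
                                   fc_up = 1.3, fc_down = 0.77) {
  prot <- nonmod_diff |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(n_nonmod = dplyr::n(),
                     nonmod_avg_ratio = mean(.data$ratio), .groups = "drop")
  out <- dplyr::left_join(panel, prot, by = "protein")
  out$protein_evidence <- ifelse(is.na(out$n_nonmod), "none", "quantified")
  out$n_nonmod <- tidyr::replace_na(out$n_nonmod, 0L)
  unaltered <- out$nonmod_avg_ratio >= fc_down & out$nonmod_avg_ratio <= fc_up
  opposite <- (out$direction == "Up" & out$nonmod_avg_ratio < 1) |
    (out$direction == "Down" & out$nonmod_avg_ratio > 1)
  out$glyco_specific <- ifelse(out$protein_evidence == "none", NA,
                               unaltered | opposite)
  out
}
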