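# Diagnostic oxonium-ion checking and mass-conserving isobaric composition
# reassignment (NeuGc -> NeuAc corrections).

#' Read a peak list
#'
#' Accepts two-column text (m/z, intensity; whitespace- or tab-separated) or
#' a single MGF-style block (`BEGIN IONS` / `END IONS` with `key=value`
#' headers ignored).
#'
#' @param path File path.
#' @return A tibble with columns `mz` and `intensity`.
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(BEGIN|END)\\s+IONS", lines, ignore.case = TRUE)]
  lines <- lines[!grepl("=", lines, fixed = TRUE)]
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "[[:space:],]+")
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad)) stop("unparsable peak line(s): ",
                     paste(utils::head(which(bad), 3), collapse = ", "),
                     call. = FALSE)
  tibble::tibble(mz = as.numeric(vapply(parts, `[[`, character(1), 1)),
                 intensity = as.numeric(vapply(parts, `[[`, character(1), 2)))
}

# peaks within tol_ppm of target m/z values
.match_peaks <- function(peaks, targets, tol_ppm) {
  hits <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    tol <- targets$mz[i] * tol_ppm * 1e-6
    sel <- abs(peaks$mz - targets$mz[i]) <= tol
    if (!any(sel)) return(tibble::tibble())
    dplyr::bind_cols(peaks[sel, ], targets[i, c("unit", "ion")],
                     tibble::tibble(theoretical_mz = targets$mz[i]))
  })
  hits
}

#' Check sialic-acid diagnostic ions in a spectrum
#'
#' Searches the peak list for the theoretical oxonium ions of NeuAc
#' (m/z 292.1027 / 274.0921) and NeuGc (m/z 308.0976 / 290.0870) within a
#' ppm tolerance. A conflict is flagged when the nominal composition contains
#' NeuGc but only NeuAc evidence is present - the signature of an isobaric
#' composition mis-assignment.
#'
#' @param spectrum A peak tibble (`mz`, `intensity`).
#' @param comp Nominal glycan composition (string or count data frame).
#' @param tol_ppm Matching tolerance in ppm (default 10).
#' @param require `"either"` (default) or `"both"`: how many of the two
#'   diagnostic ions must match to call evidence for a sialic species.
#' @return A `glyco_validation` list: `neuac_evidence`, `neugc_evidence`,
#'   `matched_peaks`, `conflict`, `composition`.
#' @examples
#' sp <- generate_spectrum("TAVNCSSDFDACLITK", "HexNAc(4)Hex(5)NeuAc(1)",
#'                         seed = 1)
#' check_diagnostic_ions(sp, "HexNAc(4)Hex(5)NeuAc(1)")
#' @export
check_diagnostic_ions <- function(spectrum, comp, tol_ppm = 10,
                                  require = c("either", "both")) {
  require <- match.arg(require)
  stopifnot(all(spectrum$mz > 0), all(spectrum$intensity >= 0))
  cnt <- parse_composition(if (is.character(comp)) comp else format_composition(comp))
  targets <- dplyr::bind_rows(oxonium_ions("NeuAc"), oxonium_ions("NeuGc"))
  hits <- .match_peaks(spectrum, targets, tol_ppm)
  evidence <- function(unit) {
    n <- if (nrow(hits) == 0) 0 else length(unique(hits$ion[hits$unit == unit]))
    if (require == "both") n == 2 else n >= 1
  }
  neuac <- evidence("NeuAc"); neugc <- evidence("NeuGc")
  structure(list(
    neuac_evidence = neuac,
    neugc_evidence = neugc,
    matched_peaks = hits,
    conflict = cnt$neugc > 0 && neuac && !neugc,
    composition = format_composition(cnt)
  ), class = "glyco_validation")
}

#' @export
print.glyco_validation <- function(x, ...) {
  cat("Diagnostic-ion validation of", x$composition, "\n")
  cat("  NeuAc evidence:", x$neuac_evidence,
      " NeuGc evidence:", x$neugc_evidence,
      " conflict:", x$conflict, "\n")
  invisible(x)
}

#' Mass-conserving reassignment of a conflicted NeuGc composition
#'
#' When diagnostic ions contradict a nominal NeuGc assignment, rewrites the
#' composition without changing the precursor mass. Two rewrites exist:
#' (a) `Fuc(-1) NeuGc(-1) -> Hex(+1) NeuAc(+1)` (preferred: exactly isobaric
#' and requires no extra modification hypothesis), else
#' (b) `NeuGc(-1) -> NeuAc(+1)` plus one added peptide oxidation (NeuGc and
#' NeuAc differ by exactly one oxygen). When a peptide sequence is supplied,
#' rewrite (b) requires an oxidizable residue (Met or Trp). The corrected
#' precursor mass is asserted to match the original within 1e-3 Da.
#'
#' @param comp Nominal composition (string or counts).
#' @param report A `glyco_validation` from [check_diagnostic_ions()], or
#'   `NULL` to force reassignment of any NeuGc-containing composition.
#' @param peptide Optional peptide sequence (gates rewrite b).
#' @param mods Character vector of current modification names.
#' @return A list: `composition` (corrected string), `mods`, `reassigned`,
#'   `unresolved`, `rule` (`"fuc_neugc"`, `"oxidation"` or `NA`),
#'   `mass_delta` (Da).
#' @examples
#' reassign_composition("HexNAc(5)Hex(6)Fuc(1)NeuAc(2)NeuGc(1)", NULL)
#' @export
reassign_composition <- function(comp, report, peptide = NULL,
                                 mods = character()) {
  cnt <- parse_composition(if (is.character(comp)) comp else format_composition(comp))
  nominal <- format_composition(cnt)
  noop <- list(composition = nominal, mods = mods, reassigned = FALSE,
               unresolved = FALSE, rule = NA_character_, mass_delta = 0)
  if (!is.null(report)) {
    stopifnot(inherits(report, "glyco_validation"))
    if (!report$conflict) return(noop)
  }
  if (cnt$neugc < 1) return(noop)
  m0 <- composition_mass(cnt) + sum(modification_mass(mods))
  if (cnt$fuc >= 1) {
    new <- cnt
    new$fuc <- new$fuc - 1L; new$neugc <- new$neugc - 1L
    new$hex <- new$hex + 1L; new$neuac <- new$neuac + 1L
    rule <- "fuc_neugc"
    new_mods <- mods
  } else if (is.null(peptide) || grepl("[MW]", peptide)) {
    new <- cnt
    new$neugc <- new$neugc - 1L; new$neuac <- new$neuac + 1L
    rule <- "oxidation"
    new_mods <- c(mods, "oxidation")
  } else {
    out <- noop
    out$unresolved <- TRUE
    return(out)
  }
  m1 <- composition_mass(new) + sum(modification_mass(new_mods))
  delta <- m1 - m0
  if (abs(delta) > 1e-3) {
    stop("reassignment does not conserve mass (delta = ", signif(delta, 3),
         " Da)", call. = FALSE)
  }
  list(composition = format_composition(new), mods = new_mods,
       reassigned = TRUE, unresolved = FALSE, rule = rule, mass_delta = delta)
}

#' Validate and correct a set of putative NeuGc glycopeptides
#'
#' Convenience wrapper: for each feature with a spectrum, runs
#' [check_diagnostic_ions()] and, on conflict, [reassign_composition()].
#'
#' @param features A tibble with columns `feature_id`, `peptide`,
#'   `composition` and a `spectrum` list-column of peak tibbles.
#' @param tol_ppm Matching tolerance in ppm.
#' @return The tibble with added `neuac_evidence`, `neugc_evidence`,
#'   `conflict`, `corrected_composition`, `added_mods`, `reassigned`,
#'   `unresolved`.
#' @export
validate_spectra <- function(features, tol_ppm = 10) {
  res <- purrr::pmap_dfr(
    features[c("peptide", "composition", "spectrum")],
    function(peptide, composition, spectrum) {
      rep <- check_diagnostic_ions(spectrum, composition, tol_ppm = tol_ppm)
      fix <- reassign_composition(composition, rep, peptide = peptide)
      tibble::tibble(
        neuac_evidence = rep$neuac_evidence,
        neugc_evidence = rep$neugc_evidence,
        conflict = rep$conflict,
        corrected_composition = fix$composition,
        added_mods = paste(setdiff(fix$mods, character(0)), collapse = ";"),
        reassigned = fix$reassigned,
        unresolved = fix$unresolved
      )
    })
  dplyr::bind_cols(features, res)
}
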