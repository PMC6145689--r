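# Packaged reference panel of differentially abundant urinary intact
# N-glycopeptides (PCa vs BPH), transcribed once from the published table and
# guarded by a checksum so accidental edits are caught at load time.

.table1_md5 <- "ced5d7fff026d361809a936013fbd505"

#' Load the packaged reference panel of differential intact N-glycopeptides
#'
#' Returns the 56-entry panel of intact N-glycopeptides differentially
#' abundant between prostate-cancer (PCa, n = 5) and benign prostatic
#' hyperplasia (BPH, n = 4) urine, spanning 21 glycoproteins. Each entry
#' carries the glycan composition counts, the limma-style q-value and the
#' PCa/BPH abundance ratio, the corroborating de-N-glycosylated (PNGase
#' F-deamidated) peptide with its own ratio, and protein-level evidence from
#' non-modified peptides (count and average ratio; `NA` where none were
#' quantified). The published table prints only the de-N peptide sequence;
#' its deamidation-stripped form is used as the intact peptide carrier, so a
#' few entries share (peptide, composition) pairs and `entry_id` is the
#' unique key.
#'
#' @param check_ratios Assert on load that every ratio passes the panel
#'   fold-change gates (> 1.3 or < 0.77); default `TRUE`.
#' @return A tibble with 56 rows and columns `entry_id`, `uniprot`, `gene`,
#'   `protein`, `hexnac`, `hex`, `fuc`, `neuac`, `neugc` (all zero: every
#'   NeuGc assignment was corrected to NeuAc after diagnostic-ion
#'   validation), `composition`, `peptide`, `q`, `ratio`, `direction`,
#'   `den_peptide`, `den_ratio`, `n_nonmod`, `nonmod_avg_ratio`.
#' @examples
#' panel <- load_table1_fixture()
#' nrow(panel)
#' dplyr::count(panel, direction)
#' @export
load_table1_fixture <- function(check_ratios = TRUE) {
  path <- system.file("extdata", "table1_panel.tsv", package = "glycopanelr",
                      mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), .table1_md5)) {
    stop("table1_panel.tsv checksum mismatch: fixture has been modified",
         call. = FALSE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$neugc <- 0L
  tab$composition <- format_composition(tab)
  tab$peptide <- strip_deamidation(tab$den_peptide)
  if (check_ratios && !all(tab$ratio > 1.3 | tab$ratio < 0.77)) {
    stop("fixture contains a ratio inside the (0.77, 1.3) exclusion band",
         call. = FALSE)
  }
  stopifnot(nrow(tab) == 56, length(unique(tab$uniprot)) == 21)
  dplyr::relocate(tab, "entry_id", "uniprot", "gene", "protein", "peptide",
                  "composition")
}

#' Default serum-glycoform whitelist
#'
#' The panel-selection cascade only admits glycoforms whose composition is a
#' commonly observed human serum glycoform. The curated public resource the
#' concept derives from is not redistributable, so the packaged default is a
#' synthetic stand-in: the set of unique compositions occurring in
#' [load_table1_fixture()]. Replace it with your own composition vector for
#' real analyses.
#'
#' @return Character vector of canonical composition strings.
#' @examples
#' head(default_glycoform_whitelist())
#' @export
default_glycoform_whitelist <- function() {
  unique(load_table1_fixture(check_ratios = FALSE)$composition)
}

#' Strip deamidation markers from a de-N peptide annotation
#'
#' De-N-glycosylated peptides are written with `(de)` after the formerly
#' glycosylated Asn, e.g. `"SVVAPATDGGLN(de)LTSTFLR"`.
#'
#' @param x Character vector of annotated sequences.
#' @return The plain sequences.
#' @export
strip_deamidation <- function(x) gsub("\\(de\\)", "", x)

#' Deamidated positions of a de-N peptide annotation
#'
#' @param x Character vector of annotated sequences (see
#'   [strip_deamidation()]).
#' @return A list of integer vectors: 1-based positions (in the stripped
#'   sequence) of residues marked `(de)`.
#' @export
deamidated_positions <- function(x) {
  lapply(x, function(s) {
    if (is.na(s)) return(integer(0))
    pos <- integer(0)
    stripped <- 0L
    rest <- s
    repeat {
      m <- regexpr("\\(de\\)", rest)
      if (m == -1) break
      pos <- c(pos, stripped + as.integer(m) - 1L)
      stripped <- stripped + as.integer(m) - 1L
      rest <- substring(rest, as.integer(m) + attr(m, "match.length"))
    }
    pos
  })
}

#' Share of features identified by both of two enrichment strategies
#'
#' Overlap arithmetic for complementary enrichment comparisons: given the
#' feature identifiers recovered by two preparations (or the already-counted
#' sizes), the shared identifications as a percentage of the combined unique
#' total.
#'
#' @param a,b Character vectors of feature identifiers, or (when `counts` is
#'   used) nothing.
#' @param counts Optionally a named list/vector with `n_shared` and `n_total`
#'   when only printed counts are available.
#' @return A tibble with `n_shared`, `n_total` and `share_pct` (= 100 *
#'   n_shared / n_total).
#' @examples
#' enrichment_overlap(c("a", "b", "c"), c("b", "c", "d"))
#' enrichment_overlap(counts = c(n_shared = 216, n_total = 954))
#' @export
enrichment_overlap <- function(a = NULL, b = NULL, counts = NULL) {
  if (!is.null(counts)) {
    n_shared <- as.numeric(counts[["n_shared"]])
    n_total <- as.numeric(counts[["n_total"]])
  } else {
    a <- unique(a); b <- unique(b)
    n_shared <- length(intersect(a, b))
    n_total <- length(union(a, b))
  }
  stopifnot(n_total > 0, n_shared <= n_total)
  tibble::tibble(n_shared = n_shared, n_total = n_total,
                 share_pct = 100 * n_shared / n_total)
}
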