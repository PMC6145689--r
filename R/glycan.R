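# Glycan composition algebra: parsing, masses, classification, oxonium ions,
# isobaric collision enumeration and N-glycosylation sequon detection.

.glycan_names <- c(hexnac = "HexNAc", hex = "Hex", fuc = "Fuc",
                   neuac = "NeuAc", neugc = "NeuGc")
.count_cols <- names(.glycan_names)

#' Parse glycan composition strings
#'
#' Parses compositions written in the `Name(count)` dialect, e.g.
#' `"HexNAc(5)Hex(6)Fuc(1)NeuAc(3)"`, into monosaccharide counts. Recognised
#' names are HexNAc, Hex, Fuc, NeuAc and NeuGc; absent names mean a count of
#' zero. Parsing is order-insensitive; [format_composition()] writes the
#' canonical order HexNAc, Hex, Fuc, NeuAc, NeuGc, and the two functions
#' round-trip.
#'
#' @param text Character vector of composition strings.
#' @param allow_empty Keep all-zero compositions instead of erroring. An
#'   all-zero composition cannot describe a glycan-bearing feature, so the
#'   default rejects it.
#' @return A tibble with one row per input string and integer columns
#'   `hexnac`, `hex`, `fuc`, `neuac`, `neugc`.
#' @examples
#' parse_composition("HexNAc(5)Hex(6)Fuc(1)NeuAc(3)")
#' parse_composition("HexNAc(2)Hex(2)")
#' @seealso [format_composition()], [composition_mass()], [classify_glycan()]
#' @export
parse_composition <- function(text, allow_empty = FALSE) {
  stopifnot(is.character(text))
  one <- function(s) {
    counts <- stats::setNames(integer(length(.count_cols)), .count_cols)
    if (is.na(s)) return(counts + NA_integer_)
    tokens <- regmatches(s, gregexpr("[A-Za-z]+\\((-?[0-9.]+)\\)", s))[[1]]
    residue <- paste(tokens, collapse = "")
    if (gsub("\\s", "", s) != residue || (length(tokens) == 0 && nzchar(s))) {
      stop("malformed composition string: '", s, "'", call. = FALSE)
    }
    for (tok in tokens) {
      name <- sub("\\(.*$", "", tok)
      num  <- sub("^.*\\(", "", sub("\\)$", "", tok))
      key  <- names(.glycan_names)[match(name, .glycan_names)]
      if (is.na(key)) {
        stop("unknown monosaccharide name in token '", tok, "'", call. = FALSE)
      }
      val <- suppressWarnings(as.numeric(num))
      if (is.na(val) || val < 0 || val != round(val)) {
        stop("invalid count in token '", tok, "'", call. = FALSE)
      }
      dup <- sum(vapply(tokens, function(t) identical(sub("\\(.*$", "", t), name), logical(1)))
      if (dup > 1) {
        stop("duplicated monosaccharide name '", name, "' in '", s, "'", call. = FALSE)
      }
      counts[key] <- as.integer(val)
    }
    counts
  }
  out <- tibble::as_tibble(do.call(rbind, lapply(text, one)))
  if (!allow_empty && any(rowSums(out, na.rm = TRUE) < 1 & !is.na(out$hexnac))) {
    stop("empty glycan composition (all counts zero) for a glycan-bearing feature",
         call. = FALSE)
  }
  out
}

#' Format glycan compositions canonically
#'
#' @param comp A data frame with columns `hexnac`, `hex`, `fuc`, `neuac`,
#'   `neugc` (e.g. from [parse_composition()]), or a character vector of
#'   composition strings (re-canonicalised).
#' @return Character vector in canonical `Name(count)` order; zero counts are
#'   omitted.
#' @examples
#' format_composition(parse_composition("NeuAc(3)Hex(6)HexNAc(5)Fuc(1)"))
#' @export
format_composition <- function(comp) {
  comp <- .as_composition(comp)
  apply(comp[.count_cols], 1, function(cc) {
    keep <- which(cc > 0)
    paste0(.glycan_names[names(cc)[keep]], "(", cc[keep], ")", collapse = "")
  })
}

# coerce character / data frame input to a count data frame
.as_composition <- function(comp, allow_empty = TRUE) {
  if (is.character(comp)) {
    return(parse_composition(comp, allow_empty = allow_empty))
  }
  stopifnot(is.data.frame(comp), all(.count_cols %in% names(comp)))
  comp
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of count-weighted residue masses. Additive:
#' `composition_mass(a) + composition_mass(b)` equals the mass of the combined
#' composition.
#'
#' @inheritParams format_composition
#' @return Numeric vector of masses in Da (0 for an all-zero composition).
#' @examples
#' composition_mass("HexNAc(2)Hex(3)")
#' # the Fuc+NeuGc vs Hex+NeuAc isobaric pair
#' composition_mass(c("Fuc(1)NeuGc(1)", "Hex(1)NeuAc(1)"))
#' @export
composition_mass <- function(comp) {
  comp <- .as_composition(comp)
  as.numeric(as.matrix(comp[.count_cols]) %*% .glycan_residue_mass[.count_cols])
}

#' Theoretical m/z of a (glyco)peptide ion
#'
#' `(peptide residue masses + water + modification masses + glycan mass +
#' charge * proton) / charge`. Monotone decreasing in charge.
#'
#' @param peptide Character vector of peptide sequences (20 standard residues).
#' @param mods A character vector of modification names (recycled to all
#'   peptides) or a list of such vectors, one per peptide; names as in
#'   [modification_mass()]. Repeat a name for multiple occurrences.
#' @param comp Glycan composition (string, count data frame, or `NULL` for
#'   none).
#' @param charge Positive integer charge state(s).
#' @return Numeric vector of m/z values.
#' @examples
#' glycopeptide_mz("K", charge = 1)
#' glycopeptide_mz("SVVAPATDGGLNLTSTFLR", mods = "tmt",
#'                 comp = "HexNAc(5)Hex(6)Fuc(1)NeuAc(3)", charge = 3)
#' @export
glycopeptide_mz <- function(peptide, mods = NULL, comp = NULL, charge = 1L) {
  stopifnot(all(charge >= 1))
  n <- max(length(peptide), length(charge))
  peptide <- rep_len(peptide, n)
  charge <- rep_len(charge, n)
  if (!is.list(mods)) mods <- rep_len(list(mods), n) else mods <- rep_len(mods, n)
  modmass <- vapply(mods, function(m) {
    if (is.null(m) || length(m) == 0) 0 else sum(modification_mass(m))
  }, numeric(1))
  gmass <- if (is.null(comp)) 0 else composition_mass(comp)
  (.peptide_mass(peptide) + modmass + gmass + charge * PROTON_MASS) / charge
}

#' Classify a glycan composition into the five reporting classes
#'
#' Partition used for class-level abundance comparisons: high-mannose
#' (`hexnac == 2`, `hex >= 5`, no Fuc, no sialic acid), then complex/hybrid
#' subdivided by terminal features into `C/H` (afucosylated/asialylated),
#' `C/H+Fuc`, `C/H+NeuAc` (sialylated: NeuAc or NeuGc), and `C/H+Fuc/Sia`.
#' Paucimannosidic/truncated compositions (e.g. HexNAc(2)Hex(2)) fall into
#' `C/H`, keeping the partition total and five-way.
#'
#' @inheritParams format_composition
#' @return Character vector with values in `c("high-mannose", "C/H",
#'   "C/H+Fuc", "C/H+NeuAc", "C/H+Fuc/Sia")`.
#' @examples
#' classify_glycan(c("HexNAc(2)Hex(9)", "HexNAc(5)Hex(6)Fuc(1)NeuAc(3)",
#'                   "HexNAc(2)Hex(2)"))
#' @export
classify_glycan <- function(comp) {
  comp <- .as_composition(comp, allow_empty = FALSE)
  if (any(rowSums(comp[.count_cols]) < 1)) {
    stop("cannot classify an empty glycan composition", call. = FALSE)
  }
  sia <- comp$neuac + comp$neugc
  dplyr::case_when(
    comp$hexnac == 2 & comp$hex >= 5 & comp$fuc == 0 & sia == 0 ~ "high-mannose",
    comp$fuc > 0 & sia > 0  ~ "C/H+Fuc/Sia",
    comp$fuc > 0            ~ "C/H+Fuc",
    sia > 0                 ~ "C/H+NeuAc",
    TRUE                    ~ "C/H"
  )
}

#' Glycan class levels
#' @return The five class labels in display order.
#' @export
glycan_classes <- function() {
  c("high-mannose", "C/H", "C/H+Fuc", "C/H+NeuAc", "C/H+Fuc/Sia")
}

#' Oxonium (diagnostic) ion m/z values
#'
#' For each monosaccharide, the singly protonated oxonium ion
#' `[residue + H]+` and its water loss `[residue + H - H2O]+`. These low-mass
#' HCD fragments report monosaccharide content, e.g. m/z 292.10/274.09 for
#' NeuAc and 308.10/290.09 for NeuGc, and are the basis of sialic-species
#' validation in [check_diagnostic_ions()].
#'
#' @param unit Character vector of monosaccharide names (`"HexNAc"`, `"Hex"`,
#'   `"Fuc"`, `"NeuAc"`, `"NeuGc"`) or a composition (string/count data
#'   frame), in which case ions of every monosaccharide present are returned.
#' @return A tibble with columns `unit`, `ion` (`"M+H"` or `"M+H-H2O"`) and
#'   `mz`.
#' @examples
#' oxonium_ions("NeuAc")
#' oxonium_ions("HexNAc(4)Hex(5)NeuAc(1)")
#' @export
oxonium_ions <- function(unit) {
  if (is.character(unit) && all(unit %in% .glycan_names)) {
    keys <- names(.glycan_names)[match(unit, .glycan_names)]
  } else if (is.character(unit) && !all(grepl("\\(", unit))) {
    stop("unsupported monosaccharide unit: ",
         paste(setdiff(unit, .glycan_names), collapse = ", "), call. = FALSE)
  } else {
    comp <- .as_composition(unit)
    if (nrow(comp) != 1) stop("supply a single composition", call. = FALSE)
    keys <- .count_cols[as.numeric(comp[1, .count_cols]) > 0]
    if (length(keys) == 0) stop("unsupported or empty unit", call. = FALSE)
  }
  res <- .glycan_residue_mass[keys]
  tibble::tibble(
    unit = rep(.glycan_names[keys], each = 2),
    ion  = rep(c("M+H", "M+H-H2O"), length(keys)),
    mz   = as.numeric(rbind(res + PROTON_MASS, res + PROTON_MASS - WATER_MASS))
  )
}

#' Default composition search space for collision enumeration
#'
#' Per-monosaccharide maximum counts spanning the compositions observed in
#' urinary N-glycopeptide searches.
#' @return Named integer vector of maxima.
#' @export
default_composition_space <- function() {
  c(hexnac = 9L, hex = 10L, fuc = 3L, neuac = 4L, neugc = 1L)
}

#' Enumerate isobaric composition collisions
#'
#' All compositions in a bounded search space whose monoisotopic mass lies
#' within `tol_ppm` of the query's mass (the query itself excluded). The
#' relation is symmetric. The canonical urinary confounds are
#' Fuc(1)NeuGc(1) vs Hex(1)NeuAc(1) (identical within < 1e-5 Da), which makes
#' e.g. HexNAc(5)Hex(6)Fuc(1)NeuAc(2)NeuGc(1) indistinguishable by mass from
#' HexNAc(5)Hex(7)NeuAc(3).
#'
#' @inheritParams format_composition
#' @param space Named integer vector of per-monosaccharide maxima, as
#'   [default_composition_space()].
#' @param tol_ppm Mass tolerance in parts per million (> 0); default 10.
#' @return A tibble of colliding compositions with their `composition` string,
#'   counts, `mass` and `delta_ppm` relative to the query.
#' @examples
#' find_isobaric_collisions("HexNAc(5)Hex(7)NeuAc(3)")
#' @export
find_isobaric_collisions <- function(comp, space = default_composition_space(),
                                     tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  comp <- .as_composition(comp, allow_empty = FALSE)
  if (nrow(comp) != 1) stop("supply a single composition", call. = FALSE)
  space <- space[.count_cols]
  grid <- expand.grid(
    hexnac = 0:space[["hexnac"]], hex = 0:space[["hex"]],
    fuc = 0:space[["fuc"]], neuac = 0:space[["neuac"]],
    neugc = 0:space[["neugc"]], KEEP.OUT.ATTRS = FALSE
  )
  grid <- tibble::as_tibble(grid)
  grid <- grid[rowSums(grid) >= 1, ]
  target <- composition_mass(comp)
  grid$mass <- composition_mass(grid)
  grid$delta_ppm <- (grid$mass - target) / target * 1e6
  same <- rowSums(abs(sweep(as.matrix(grid[.count_cols]), 2,
                            as.numeric(comp[1, .count_cols])))) == 0
  hits <- grid[abs(grid$delta_ppm) <= tol_ppm & !same, ]
  dplyr::bind_cols(
    tibble::tibble(composition = format_composition(hits)),
    hits
  )
}

# 1-based sequon start positions in one sequence: N, x != P, then S/T/C
.sequon_positions <- function(seq) {
  if (is.na(seq) || nchar(seq) < 3) return(integer(0))
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  idx <- which(aa[seq_len(n - 2)] == "N")
  idx[aa[idx + 1] != "P" & aa[idx + 2] %in% c("S", "T", "C")]
}

#' Find N-glycosylation sequons
#'
#' Locates the conserved N-glycosylation motif N-X-S/T/C with X != P.
#'
#' @param peptide Character vector of sequences.
#' @return A tibble with columns `peptide` and `position` (1-based position of
#'   the sequon Asn); sequences without a sequon contribute no rows.
#' @examples
#' find_sequons(c("LNAENNATFYFK", "TAVNCSSDFDACLITK", "NPT"))
#' @export
find_sequons <- function(peptide) {
  stopifnot(is.character(peptide))
  purrr::map_dfr(peptide, function(p) {
    pos <- .sequon_positions(p)
    if (length(pos) == 0) return(tibble::tibble(peptide = character(0),
                                                position = integer(0)))
    tibble::tibble(peptide = p, position = pos)
  })
}
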