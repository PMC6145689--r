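# Monoisotopic mass bookkeeping. All masses are carried at full precision
# internally; three-decimal values in documentation are display rounding.

.element_mass <- c(
  H   = 1.0078250319,
  C   = 12.0,
  C13 = 13.0033548378,
  N   = 14.0030740052,
  N15 = 15.0001088984,
  O   = 15.9949146221,
  S   = 31.97207069
)

.formula_mass <- function(counts) {
  sum(.element_mass[names(counts)] * counts)
}

PROTON_MASS <- 1.007276467
WATER_MASS  <- .formula_mass(c(H = 2, O = 1))

# Glycan residue (dehydrated monosaccharide) masses, from elemental composition
.glycan_residue_mass <- c(
  hexnac = .formula_mass(c(C = 8,  H = 13, N = 1, O = 5)),  # 203.079373
  hex    = .formula_mass(c(C = 6,  H = 10, O = 5)),         # 162.052824
  fuc    = .formula_mass(c(C = 6,  H = 10, O = 4)),         # 146.057909 (deoxyhexose)
  neuac  = .formula_mass(c(C = 11, H = 17, N = 1, O = 8)),  # 291.095417
  neugc  = .formula_mass(c(C = 11, H = 17, N = 1, O = 9))   # 307.090331
)

# 20 standard amino-acid residue masses
.aa_residue_mass <- c(
  G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527639,
  V = 99.0684139, T = 101.0476785, C = 103.0091845, L = 113.0840640,
  I = 113.0840640, N = 114.0429274, D = 115.0269430, Q = 128.0585775,
  K = 128.0949630, E = 129.0425931, M = 131.0404846, H = 137.0589119,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793130
)

# Peptide modifications, from elemental composition. TMT10 uses the
# isotope-coded reagent (4x 13C, 1x 15N).
.modification_formula <- list(
  carbamidomethyl = c(C = 2, H = 3, N = 1, O = 1),                 # +57.021464
  oxidation       = c(O = 1),                                      # +15.994915
  deamidation     = c(O = 1, N = -1, H = -1),                      # +0.984016
  tmt             = c(C = 8, C13 = 4, H = 20, N = 1, N15 = 1, O = 2) # +229.162932
)

.modification_mass <- vapply(.modification_formula, .formula_mass, numeric(1))

#' Monoisotopic modification masses
#'
#' Mass additions for the peptide modifications used throughout the package,
#' computed from elemental composition: carbamidomethyl-Cys (+57.021 Da),
#' Met oxidation (+15.994 Da), Asn/Gln deamidation (+0.984 Da, the signature
#' left on a former N-glycosite by PNGase F), and the TMT10 isobaric label
#' (+229.163 Da at N-terminus and Lys).
#'
#' @param name Optional modification name(s); one of `"carbamidomethyl"`,
#'   `"oxidation"`, `"deamidation"`, `"tmt"`. With `NULL` (default) all are
#'   returned.
#' @return A named numeric vector of monoisotopic mass additions in Da.
#' @examples
#' modification_mass("tmt")
#' modification_mass()
#' @export
modification_mass <- function(name = NULL) {
  if (is.null(name)) return(.modification_mass)
  unknown <- setdiff(name, names(.modification_mass))
  if (length(unknown) > 0) {
    stop("unknown modification(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  .modification_mass[name]
}

#' Monoisotopic glycan residue masses
#'
#' Residue (dehydrated) monoisotopic masses of the five monosaccharides of the
#' composition model: HexNAc, Hex, Fuc (deoxyhexose), NeuAc and NeuGc.
#' Two near-exact isobaric identities among these drive composition
#' mis-assignment in glycopeptide searches: NeuGc differs from NeuAc by one
#' oxygen (= a Met-oxidation mass), and Fuc + NeuGc equals Hex + NeuAc.
#'
#' @return Named numeric vector of residue masses in Da.
#' @examples
#' glycan_residue_mass()
#' @export
glycan_residue_mass <- function() .glycan_residue_mass

#' Amino-acid residue masses and fundamental constants
#'
#' @return `amino_acid_mass()`: named numeric vector of the 20 standard
#'   amino-acid residue monoisotopic masses. `mass_constants()`: proton and
#'   water monoisotopic masses.
#' @examples
#' amino_acid_mass()[["K"]]
#' mass_constants()
#' @export
amino_acid_mass <- function() .aa_residue_mass

#' @rdname amino_acid_mass
#' @export
mass_constants <- function() c(proton = PROTON_MASS, water = WATER_MASS)

# neutral monoisotopic peptide mass (residues + water); no mods
.peptide_mass <- function(peptide) {
  vapply(peptide, function(p) {
    aa <- strsplit(p, "")[[1]]
    bad <- setdiff(aa, names(.aa_residue_mass))
    if (length(bad) > 0) {
      stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
    sum(.aa_residue_mass[aa]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}
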