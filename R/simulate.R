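# Synthetic TMT10 glycoproteomics cohorts with ground truth. The generator
# emulates the statistical structure the downstream analysis assumes: PSM-level
# reporter blocks for four peptide populations (intact N-glycopeptides,
# desialo-O-glycopeptides, de-N-glycosylated peptides, non-modified peptides),
# log-normal baselines, case/control fold-changes, multiplicative channel
# noise, PSM redundancy, PIF co-isolation contamination with ratio compression,
# one globally shifted outlier control channel, feature-wise missingness and
# target/decoy score populations.

.tmt10_channels <- c("126", "127N", "127C", "128N", "128C",
                     "129N", "129C", "130N", "130C", "131")

#' Configuration for a synthetic TMT10 cohort
#'
#' Defaults emulate the urinary PCa-vs-BPH study design: 5 case channels
#' (TMT 126-128C) and 5 control channels (129N-131), one of which behaves as
#' a global outlier and is expected to be removed by PCA QC (leaving 5 vs 4),
#' 20% multiplicative channel noise, and case/control effects specified as
#' linear-scale ratios.
#'
#' @param n_case,n_control Channels per group (>= 2 each, <= 10 total).
#' @param effects Optional tibble of planted intact-N-glycopeptide effects
#'   with columns `peptide`, `composition`, `ratio` and optionally `protein`,
#'   `gene`, `den_ratio`, `n_nonmod`, `nonmod_avg_ratio` (the shape of
#'   [load_table1_fixture()]). `NULL` plants nothing (global null).
#' @param n_features Named vector: number of additional null features for the
#'   `intact_N` and `desialo_O` classes. De-N and non-modified features are
#'   derived from the intact features so that corroborating site-level and
#'   protein-level evidence exists for every intact glycopeptide.
#' @param baseline_mean,baseline_sd Log2-intensity baseline distribution.
#' @param cv Per-channel multiplicative noise, as a coefficient of variation
#'   (> 0; default 0.20).
#' @param psm_redundancy Mean PSMs per feature (Poisson-shifted, >= 1).
#' @param pif_contaminated_rate Fraction of PSMs suffering precursor
#'   co-isolation: their PIF falls below 0.75 and their reporter ratios are
#'   compressed toward 1 proportionally to (1 - PIF).
#' @param outlier_channel Control channel receiving a global log2 shift
#'   (`NULL` for none); `outlier_shift` its magnitude (default +2).
#' @param missing_rate Probability that a discovery-class feature (intact-N,
#'   desialo-O) is entirely absent from the PSM table (reporter blocks are
#'   complete per spectrum, so missingness is feature-wise). The de-N and
#'   non-modified fractions play a corroborative role and are emulated at
#'   full coverage, reflecting their deep off-line pre-fractionation.
#' @param decoy_fraction Decoy PSMs added per table, as a fraction of target
#'   PSMs; decoy scores are drawn from a separably lower distribution.
#' @param n_mislabel Number of null intact features whose nominal composition
#'   carries a spurious NeuGc (the true glycoform is the NeuAc-containing
#'   isobar); used to exercise diagnostic-ion validation.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `cohort_config` list.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$design
#' @export
cohort_config <- function(n_case = 5, n_control = 5,
                          effects = NULL,
                          n_features = c(intact_N = 300, desialo_O = 60),
                          baseline_mean = 20, baseline_sd = 1.5,
                          cv = 0.20,
                          psm_redundancy = 2,
                          pif_contaminated_rate = 0.10,
                          outlier_channel = "129N",
                          outlier_shift = 2,
                          missing_rate = 0.05,
                          decoy_fraction = 0.10,
                          n_mislabel = 5,
                          seed = 1L) {
  stopifnot(n_case >= 2, n_control >= 2, n_case + n_control <= 10, cv > 0,
            psm_redundancy >= 1, missing_rate >= 0, missing_rate < 1)
  channels <- .tmt10_channels[seq_len(n_case + n_control)]
  design <- tibble::tibble(
    channel = channels,
    group = rep(c("case", "control"), c(n_case, n_control))
  )
  if (!is.null(outlier_channel) &&
      !outlier_channel %in% design$channel[design$group == "control"]) {
    stop("outlier_channel must be a control channel", call. = FALSE)
  }
  structure(list(
    n_case = n_case, n_control = n_control, design = design,
    effects = effects, n_features = n_features,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd, cv = cv,
    psm_redundancy = psm_redundancy,
    pif_contaminated_rate = pif_contaminated_rate,
    outlier_channel = outlier_channel, outlier_shift = outlier_shift,
    missing_rate = missing_rate, decoy_fraction = decoy_fraction,
    n_mislabel = n_mislabel, seed = as.integer(seed)
  ), class = "cohort_config")
}

# random tryptic-looking peptide guaranteed to contain one sequon (N-x-S/T)
.random_sequon_peptide <- function(n = 1, len = 12) {
  aa <- c("A", "D", "E", "F", "G", "H", "I", "L", "Q", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    body <- sample(aa, len - 4, replace = TRUE)
    at <- sample(seq_len(len - 4), 1)
    seqn <- c(sample(c("A", "G", "L", "V"), 1), sample(c("S", "T"), 1))
    paste0(paste(append(body, c("N", seqn), after = at - 1), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

.random_composition <- function(n, pool) {
  sample(pool, n, replace = TRUE)
}

# log2-scale sd equivalent to a multiplicative CV
.cv_to_sdlog2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Generate a synthetic TMT cohort with ground truth
#'
#' Builds PSM-level tables for the four peptide classes plus a truth table.
#' Reporter intensities follow
#' `2^(baseline + log2(ratio) * case_indicator + outlier_shift *
#' outlier_indicator + noise)`, summed PSM structure is consistent with
#' feature-level aggregation (PSM intensities of a feature sum to its channel
#' intensity before contamination), and contaminated PSMs have their ratios
#' compressed toward 1 proportionally to (1 - PIF). Output is deterministic
#' under a fixed seed.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `psm` (named list of tibbles: `intact_N`,
#'   `desialo_O`, `de_N`, `non_modified`), `truth` (one row per generated
#'   feature: `feature_id`, `class`, `peptide`, `protein`, `composition`,
#'   `true_composition`, `true_ratio`, `true_class`, `neugc_mislabel`,
#'   `missing`), `design` and `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_features = c(intact_N = 40,
#'                                                        desialo_O = 10),
#'                                         seed = 7))
#' names(cohort$psm)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  design <- config$design
  channels <- design$channel
  is_case <- design$group == "case"

  eff <- config$effects
  if (!is.null(eff)) {
    stopifnot(all(c("peptide", "composition", "ratio") %in% names(eff)))
    if (anyNA(eff$ratio) || any(eff$ratio <= 0)) {
      stop("effect table contains invalid ratios", call. = FALSE)
    }
    if (!"protein" %in% names(eff)) eff$protein <- paste0("EFFPROT", seq_len(nrow(eff)))
    if (!"den_ratio" %in% names(eff)) eff$den_ratio <- 1
    if (!"n_nonmod" %in% names(eff)) eff$n_nonmod <- 3L
    if (!"nonmod_avg_ratio" %in% names(eff)) eff$nonmod_avg_ratio <- 1
  }

  pool <- default_glycoform_whitelist()

  # ---- intact N features: planted effects + null background -------------
  n_null <- config$n_features[["intact_N"]]
  null_prot <- paste0("NULLPROT", sprintf("%03d", seq_len(max(1, ceiling(n_null / 4)))))
  intact <- tibble::tibble(
    peptide = .random_sequon_peptide(n_null),
    composition = .random_composition(n_null, pool),
    protein = sample(null_prot, n_null, replace = TRUE),
    ratio = 1, den_ratio = 1, n_nonmod = 2L, nonmod_avg_ratio = 1,
    planted = FALSE
  )
  if (!is.null(eff)) {
    intact <- dplyr::bind_rows(
      tibble::tibble(peptide = eff$peptide, composition = eff$composition,
                     protein = eff$protein, ratio = eff$ratio,
                     den_ratio = eff$den_ratio,
                     n_nonmod = tidyr::replace_na(as.integer(eff$n_nonmod), 2L),
                     nonmod_avg_ratio = tidyr::replace_na(eff$nonmod_avg_ratio, 1),
                     planted = TRUE),
      intact
    )
  }
  # make duplicated (peptide, composition) keys unique by charge-irrelevant tag
  dup <- duplicated(paste(intact$peptide, intact$composition))
  intact$peptide[dup] <- paste0(intact$peptide[dup], "K")

  # NeuGc mislabels among null features: nominal = Hex-1 NeuAc-1 Fuc+1 NeuGc+1
  intact$true_composition <- intact$composition
  intact$neugc_mislabel <- FALSE
  cnt <- parse_composition(intact$composition)
  eligible <- which(!intact$planted & cnt$hex >= 1 & cnt$neuac >= 1)
  mis <- utils::head(eligible, config$n_mislabel)
  if (length(mis) > 0) {
    mc <- cnt[mis, ]
    mc$hex <- mc$hex - 1L; mc$neuac <- mc$neuac - 1L
    mc$fuc <- mc$fuc + 1L; mc$neugc <- mc$neugc + 1L
    intact$composition[mis] <- format_composition(mc)
    intact$neugc_mislabel[mis] <- TRUE
  }

  # ---- desialo-O features (class-level context only) --------------------
  n_o <- config$n_features[["desialo_O"]]
  o_feat <- tibble::tibble(
    peptide = .random_sequon_peptide(n_o, len = 14),
    composition = sample(c("HexNAc(3)Hex(1)Fuc(1)", "HexNAc(2)Hex(1)",
                           "HexNAc(1)Hex(1)", "HexNAc(2)Hex(2)Fuc(1)"),
                         n_o, replace = TRUE),
    protein = sample(null_prot, n_o, replace = TRUE),
    ratio = 1
  )

  # ---- de-N features: one per unique intact (protein, peptide) ----------
  den <- dplyr::distinct(intact, .data$protein, .data$peptide, .data$den_ratio)
  den_pos <- vapply(den$peptide, function(p) .sequon_positions(p)[1], integer(1))
  den$den_peptide <- paste0(substr(den$peptide, 1, den_pos), "(de)",
                            substr(den$peptide, den_pos + 1, nchar(den$peptide)))

  # ---- non-modified features: per protein ------------------------------
  prot <- dplyr::distinct(intact, .data$protein, .data$n_nonmod,
                          .data$nonmod_avg_ratio)
  prot <- prot[!duplicated(prot$protein), ]
  nonmod <- tidyr::uncount(prot, weights = pmax(.data$n_nonmod, 1L))
  nonmod$peptide <- .random_sequon_peptide(nrow(nonmod), len = 10)

  sd2 <- .cv_to_sdlog2(config$cv)
  shift <- ifelse(channels == (config$outlier_channel %||% ""),
                  config$outlier_shift, 0)

  draw_class <- function(feat, class, composition = TRUE, pep2d_filtered = TRUE,
                         peptide_col = "peptide", missing_rate = 0) {
    n <- nrow(feat)
    if (n == 0) return(tibble::tibble())
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    log2fc <- log2(feat$ratio)
    missing <- stats::runif(n) < missing_rate
    rows <- purrr::map(seq_len(n), function(i) {
      if (missing[i]) return(NULL)
      mu <- baseline[i] + log2fc[i] * is_case + shift
      eps <- stats::rnorm(length(channels), 0, sd2)
      linear <- 2^(mu + eps)
      n_psm <- 1L + stats::rpois(1, config$psm_redundancy - 1)
      w <- stats::rexp(n_psm); w <- w / sum(w)
      contaminated <- stats::runif(n_psm) < config$pif_contaminated_rate
      pif <- ifelse(contaminated, stats::runif(n_psm, 0.30, 0.75),
                    stats::runif(n_psm, 0.90, 1.00))
      bad_target <- stats::runif(n_psm) < 0.02
      pep2d <- ifelse(bad_target, 10^stats::runif(n_psm, -2.8, -1.5),
                      10^stats::runif(n_psm, -6, -3.2))
      ints <- purrr::map(seq_len(n_psm), function(j) {
        own <- linear * w[j]
        if (contaminated[j]) {
          pif[j] * own + (1 - pif[j]) * mean(own)  # co-isolation compresses ratios
        } else own
      })
      m <- do.call(rbind, ints)
      colnames(m) <- channels
      dplyr::bind_cols(
        tibble::tibble(
          peptide = feat[[peptide_col]][i],
          mods = "tmt",
          composition = if (composition) feat$composition[i] else NA_character_,
          protein = feat$protein[i],
          charge = sample(2:4, n_psm, replace = TRUE),
          score = stats::rnorm(n_psm, 300, 30),
          pep2d = if (pep2d_filtered) pep2d else NA_real_,
          pif = pif,
          decoy = FALSE,
          rt = stats::runif(n_psm, 20, 80)
        ),
        tibble::as_tibble(m)
      )
    })
    psm <- dplyr::bind_rows(rows)
    # decoys: reversed peptides, separably lower scores
    n_decoy <- ceiling(nrow(psm) * config$decoy_fraction)
    if (n_decoy > 0) {
      idx <- sample(nrow(psm), n_decoy, replace = TRUE)
      decoys <- psm[idx, ]
      decoys$peptide <- vapply(strsplit(decoys$peptide, ""), function(x)
        paste(rev(x), collapse = ""), character(1))
      decoys$decoy <- TRUE
      decoys$score <- stats::rnorm(n_decoy, 150, 30)
      psm <- dplyr::bind_rows(psm, decoys)
    }
    psm$spectrum_id <- paste0(class, "_", seq_len(nrow(psm)))
    attr(psm, "missing") <- missing
    dplyr::relocate(psm, "spectrum_id")
  }

  psm_intact <- draw_class(intact, "intactN", missing_rate = config$missing_rate)
  psm_o <- draw_class(o_feat, "desialoO", missing_rate = config$missing_rate)
  psm_den <- draw_class(den |> dplyr::mutate(ratio = .data$den_ratio,
                                             composition = NA_character_),
                        "deN", composition = FALSE, peptide_col = "den_peptide")
  psm_nonmod <- draw_class(nonmod |> dplyr::mutate(ratio = .data$nonmod_avg_ratio),
                           "nonmod", composition = FALSE, pep2d_filtered = FALSE)

  truth <- dplyr::bind_rows(
    tibble::tibble(
      feature_id = paste(intact$peptide, intact$composition, sep = "|"),
      class = "intact_N", peptide = intact$peptide, protein = intact$protein,
      composition = intact$composition,
      true_composition = intact$true_composition,
      true_ratio = intact$ratio,
      true_class = dplyr::case_when(intact$ratio > 1 ~ "up",
                                    intact$ratio < 1 ~ "down",
                                    TRUE ~ "null"),
      neugc_mislabel = intact$neugc_mislabel,
      planted = intact$planted,
      missing = attr(psm_intact, "missing")
    ),
    tibble::tibble(
      feature_id = paste(o_feat$peptide, o_feat$composition, sep = "|"),
      class = "desialo_O", peptide = o_feat$peptide, protein = o_feat$protein,
      composition = o_feat$composition, true_composition = o_feat$composition,
      true_ratio = o_feat$ratio, true_class = "null",
      neugc_mislabel = FALSE, planted = FALSE,
      missing = attr(psm_o, "missing")
    ),
    tibble::tibble(
      feature_id = paste(den$den_peptide, "deN", sep = "|"),
      class = "de_N", peptide = den$den_peptide, protein = den$protein,
      composition = NA_character_, true_composition = NA_character_,
      true_ratio = den$den_ratio,
      true_class = dplyr::case_when(den$den_ratio > 1 ~ "up",
                                    den$den_ratio < 1 ~ "down",
                                    TRUE ~ "null"),
      neugc_mislabel = FALSE, planted = FALSE,
      missing = attr(psm_den, "missing")
    ),
    tibble::tibble(
      feature_id = paste(nonmod$peptide, "nonmod", sep = "|"),
      class = "non_modified", peptide = nonmod$peptide,
      protein = nonmod$protein,
      composition = NA_character_, true_composition = NA_character_,
      true_ratio = nonmod$nonmod_avg_ratio,
      true_class = dplyr::case_when(nonmod$nonmod_avg_ratio > 1 ~ "up",
                                    nonmod$nonmod_avg_ratio < 1 ~ "down",
                                    TRUE ~ "null"),
      neugc_mislabel = FALSE, planted = FALSE,
      missing = attr(psm_nonmod, "missing")
    )
  )

  list(psm = list(intact_N = psm_intact, desialo_O = psm_o,
                  de_N = psm_den, non_modified = psm_nonmod),
       truth = truth, design = design, config = config)
}

#' Generate a toy HCD peak list for a glycopeptide
#'
#' Emits the oxonium ions of the feature's true glycan composition (so a
#' NeuGc-mislabelled feature shows NeuAc diagnostic ions and no NeuGc ions)
#' plus uniform background peaks kept away from the 260-320 m/z diagnostic
#' window.
#'
#' @param peptide Peptide sequence (annotation only).
#' @param composition Nominal composition string.
#' @param mislabel If `TRUE`, the true composition is the mass-conserving
#'   NeuAc isobar of the nominal NeuGc-containing composition (see
#'   [reassign_composition()]); diagnostic ions reflect the truth.
#' @param true_composition Optionally override the derived true composition.
#' @param n_background Number of background peaks.
#' @param seed Optional integer seed.
#' @return A tibble with columns `mz`, `intensity` and attribute
#'   `"peptide"`/`"composition"`.
#' @examples
#' generate_spectrum("TAVNCSSDFDACLITK", "HexNAc(4)Hex(5)NeuAc(1)",
#'                   seed = 1)
#' @export
generate_spectrum <- function(peptide, composition, mislabel = FALSE,
                              true_composition = NULL, n_background = 30,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- true_composition %||%
    (if (mislabel) .neuac_isobar(composition) else composition)
  cnt <- parse_composition(truth)
  peaks <- if (sum(cnt) > 0) oxonium_ions(truth) else
    tibble::tibble(unit = character(0), ion = character(0), mz = numeric(0))
  diag <- tibble::tibble(mz = peaks$mz,
                         intensity = stats::runif(nrow(peaks), 1e4, 1e5))
  bg_mz <- stats::runif(n_background * 2, 150, 2000)
  bg_mz <- utils::head(bg_mz[bg_mz < 260 | bg_mz > 320], n_background)
  bg <- tibble::tibble(mz = bg_mz,
                       intensity = stats::runif(length(bg_mz), 1e3, 1e4))
  out <- dplyr::arrange(dplyr::bind_rows(diag, bg), .data$mz)
  attr(out, "peptide") <- peptide
  attr(out, "composition") <- composition
  out
}

# mass-conserving NeuAc-containing isobar of a nominal NeuGc composition
.neuac_isobar <- function(composition) {
  cnt <- parse_composition(composition)
  if (cnt$neugc >= 1 && cnt$fuc >= 1) {
    cnt$fuc <- cnt$fuc - 1L; cnt$neugc <- cnt$neugc - 1L
    cnt$hex <- cnt$hex + 1L; cnt$neuac <- cnt$neuac + 1L
  } else if (cnt$neugc >= 1) {
    cnt$neugc <- cnt$neugc - 1L; cnt$neuac <- cnt$neuac + 1L
  }
  format_composition(cnt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
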