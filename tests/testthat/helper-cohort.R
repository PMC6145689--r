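# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, maker(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full-size cohort carrying the reference-panel fold-changes (5v5 channels,
# one outlier control channel, 1,000 null intact features)
table1_cohort <- function(seed = 42) {
  cached(paste0("cohort_", seed), function() {
    simulate_cohort(cohort_config(
      effects = load_table1_fixture(),
      n_features = c(intact_N = 1000, desialo_O = 60),
      seed = seed))
  })
}

table1_pipeline <- function(seed = 42) {
  cached(paste0("pipeline_", seed), function() {
    cohort <- table1_cohort(seed)
    suppressWarnings(run_pipeline(cohort$psm, cohort$design,
                                  panel_sizes = c(20, 28, 56)))
  })
}

# small log2-scale quant matrix from a plain matrix (samples in columns)
qm_from_matrix <- function(m, log2_scale = TRUE) {
  ch <- c("126", "127N", "127C", "128N", "128C",
          "129N", "129C", "130N", "130C", "131")[seq_len(ncol(m))]
  qm <- tibble::tibble(feature_id = paste0("f", seq_len(nrow(m))))
  for (i in seq_along(ch)) qm[[ch[i]]] <- m[, i]
  attr(qm, "log2_scale") <- log2_scale
  qm
}

design_for <- function(n_case, n_control) {
  ch <- c("126", "127N", "127C", "128N", "128C",
          "129N", "129C", "130N", "130C", "131")[seq_len(n_case + n_control)]
  tibble::tibble(channel = ch,
                 group = rep(c("case", "control"), c(n_case, n_control)))
}

# vector with exact mean and sd (for summary-statistic fixtures)
vector_with_moments <- function(n, mean, sd) {
  base <- seq_len(n)
  base <- (base - mean(base)) / stats::sd(base)
  base * sd + mean
}
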