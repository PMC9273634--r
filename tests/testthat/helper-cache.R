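# memoized fixtures shared across test files (built once per test run)

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# static resource bundle (genome + transcripts + annotation tables)
shared_resources <- function() memo("resources", generate_resources(seed = 1L))

# the packaged default cohort: 150 trios, 20 planted QC failures, seed 1 —
# the worked example behind the QC acceptance criterion
default_sim <- function() memo("default_sim", generate_cohort(cohort_spec()))

default_qc <- function() memo("default_qc", apply_qc(default_sim()$cohort))

default_dnm <- function() memo("default_dnm",
  discover_dnms(default_qc()$retained_cohort, default_sim()$resources))

# a small clean cohort for fast structural tests
small_spec <- function(seed = 7L, ...) {
  cohort_spec(n_trios = 8L,
              n_qc_fail = c(missingness = 0L, sex_mismatch = 0L,
                            relatedness = 0L, mendelian_outlier = 0L),
              decoys_per_class = c(low_gq = 1L, low_dp = 1L, inherited = 1L,
                                   common_maf = 1L, noncoding = 1L,
                                   parent_missing = 1L),
              n_background_sites = 400L, n_x_sites = 400L, seed = seed, ...)
}

small_sim <- function() memo("small_sim",
  generate_cohort(small_spec(), resources = shared_resources()))

extdata <- function(...) {
  p <- system.file("extdata", ..., package = "denovotrio")
  if (!nzchar(p)) p <- file.path(testthat::test_path("..", "..", "inst",
                                                     "extdata"), ...)
  p
}
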