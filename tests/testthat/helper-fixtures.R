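# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# A small preprocessed cohort shared by several test files.
small_mdp <- function() {
  if (is.null(.fixture_env$small)) {
    co <- generate_cohort(cohort_config(n_patients = 120, seed = 42))
    mdp <- preprocess_cohort(co$records, co$outcomes, seed = 7)
    .fixture_env$small <- list(cohort = co, mdp = mdp)
  }
  .fixture_env$small
}

# Hand-built records for one patient.
make_records <- function(patient_id, feature, time, value) {
  data.frame(patient_id = patient_id, block_time_hours = time,
             feature = feature, value = value)
}

# Independent quantile oracle: linear interpolation between order statistics
# at h = (n + 1) * p (the definition the action bins use), computed by
# brute-force sorting.
interp_quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  sapply(p, function(pp) {
    h <- (n + 1) * pp
    lo <- floor(h)
    if (lo < 1) return(x[1])
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  })
}
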