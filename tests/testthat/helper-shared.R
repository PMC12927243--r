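# Shared fixtures. The default-conditions cohort and pipeline run are
# computed once per test session and reused by the tests that exercise
# study-scale behaviour.

.shared <- new.env(parent = emptyenv())

shared_default_run <- function() {
  if (is.null(.shared$run)) {
    .shared$run <- run_pipeline(sim_config(rng_seed = 42), fit_models = FALSE)
  }
  .shared$run
}

# A small, fast cohort for unit tests.
small_config <- function(...) {
  sim_config(n_fish = 12, n_stations_sea = 30,
             study_end = "2020-04-30", rng_seed = 5, ...)
}

shared_small_cohort <- function() {
  if (is.null(.shared$small)) .shared$small <- simulate_cohort(small_config())
  .shared$small
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Detection tibble shorthand.
det_tbl <- function(ts, array, tag = "f1") {
  tibble::tibble(timestamp = as_utc_t(ts), array_id = array, tag_id = tag)
}
as_utc_t <- function(x) {
  if (is.numeric(x)) as.POSIXct(x, origin = "2020-01-01 00:00:00", tz = "UTC")
  else as.POSIXct(x, tz = "UTC")
}
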