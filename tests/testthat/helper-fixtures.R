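# Fixture builders and a session-level cache for the default synthetic
# cohort (simulated once, reused across test files).

t0 <- function(min = 0, sec = 0) {
  as.POSIXct("2024-03-04 10:00:00", tz = "UTC") + min * 60 + sec
}

make_stream <- function(hr, step_s, id = "P01", age = 25, role = if (step_s == 60) "test" else "reference",
                        start = t0()) {
  sensor_stream(id, age, role, start + (seq_along(hr) - 1) * step_s, hr)
}

# One clock minute of 10-s reference samples for each element of `values`
# (a list of length-6 vectors), plus a test stream of per-minute values.
paired_fixture <- function(test_values, ref_minutes, id = "P01", age = 25) {
  stopifnot(length(test_values) == length(ref_minutes))
  test <- make_stream(test_values, 60, id = id, age = age, role = "test")
  ref_hr <- unlist(ref_minutes)
  ref <- make_stream(ref_hr, 10, id = id, age = age, role = "reference")
  list(test = test, reference = ref)
}

.cohort_cache <- new.env(parent = emptyenv())

# Default validation-only cohort (10 participants, one 3-6 h paired session
# each), simulated once per test run.
default_validation_cohort <- function(seed = 42) {
  key <- paste0("c", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(
      cohort_scenario(followup_days = 0, seed = seed))
  }
  .cohort_cache[[key]]
}

cohort_pairs <- function(cohort) {
  pool_pairs(lapply(Filter(Negate(is.null), cohort$validation),
                    function(v) pair_streams(v$test, v$reference)))
}
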