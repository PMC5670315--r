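#' Activity-state model for the synthetic cohort
#'
#' Free-living activity is modelled as a semi-Markov chain over four states:
#' device nonwear, rest, light activity and MVPA bouts. Dwell times are
#' exponential with the given means; within a bout the true heart rate
#' mean-reverts towards a bout-specific target. Targets for `light` and
#' `mvpa` are drawn uniformly from the given relative-intensity ranges
#' (fractions of age-predicted maximal heart rate); the `rest` target is
#' anchored at the participant's resting heart rate (see
#' [cohort_scenario()]), which for a young adult cohort corresponds to about
#' 0.33-0.38 of maximal heart rate, below the light range.
#'
#' @param dwell_min named numeric vector of mean dwell times in minutes.
#' @param intensity_lo,intensity_hi named numeric vectors of relative-intensity
#'   target bounds for `light` and `mvpa`.
#' @return A list of class `activity_states`.
#' @export
activity_states <- function(dwell_min = c(nonwear = 12, rest = 30, light = 10, mvpa = 6),
                            intensity_lo = c(light = 0.40, mvpa = 0.62),
                            intensity_hi = c(light = 0.47, mvpa = 0.90)) {
  stopifnot(all(c("nonwear", "rest", "light", "mvpa") %in% names(dwell_min)))
  if (intensity_hi["light"] >= 0.5 || intensity_lo["mvpa"] < 0.5) {
    stopf("light range must lie below 0.5 and mvpa range at or above 0.5")
  }
  structure(list(dwell_min = dwell_min, intensity_lo = intensity_lo,
                 intensity_hi = intensity_hi),
            class = "activity_states")
}

default_transitions <- function() {
  states <- c("nonwear", "rest", "light", "mvpa")
  P <- matrix(0, 4, 4, dimnames = list(states, states))
  P["nonwear", c("rest", "light")] <- c(0.8, 0.2)
  P["rest", c("light", "mvpa", "nonwear")] <- c(0.70, 0.15, 0.15)
  P["light", c("rest", "mvpa", "nonwear")] <- c(0.60, 0.30, 0.10)
  P["mvpa", c("rest", "light")] <- c(0.40, 0.60)
  P
}

#' Device error model for the synthetic cohort
#'
#' Additive test-device error with participant-level heterogeneity: each
#' participant i receives a bias intercept `b0_i ~ N(bias_intercept_mean,
#' bias_intercept_sd)` (bpm) and an intensity slope `b1_i ~ N(bias_slope_mean,
#' bias_slope_sd)` (bpm per bpm above resting heart rate), so the expected
#' test-minus-truth error at true heart rate h is
#' `b0_i + b1_i * max(0, h - rest_i)`. Both devices add white measurement
#' noise, and both drop readings to 0 at the given per-sample probabilities.
#' The defaults make the underestimate roughly −4 bpm at low intensity and in
#' the mid-teens within the MVPA zone.
#'
#' @param bias_intercept_mean,bias_intercept_sd bpm.
#' @param bias_slope_mean,bias_slope_sd bpm per bpm above rest.
#' @param noise_sd_test,noise_sd_reference bpm.
#' @param test_dropout_prob per-minute probability of a missing test reading.
#' @param reference_dropout_prob per-10-s-sample probability of a missing
#'   reference reading.
#' @return A list of class `device_error_model`.
#' @export
device_error_model <- function(bias_intercept_mean = -4, bias_intercept_sd = 1.3,
                               bias_slope_mean = -0.15, bias_slope_sd = 0.04,
                               noise_sd_test = 3, noise_sd_reference = 1.5,
                               test_dropout_prob = 0.04,
                               reference_dropout_prob = 0.02) {
  stopifnot(noise_sd_test >= 0, noise_sd_reference >= 0,
            test_dropout_prob >= 0, test_dropout_prob <= 1,
            reference_dropout_prob >= 0, reference_dropout_prob <= 1,
            bias_intercept_sd >= 0, bias_slope_sd >= 0)
  structure(list(bias_intercept_mean = bias_intercept_mean,
                 bias_intercept_sd = bias_intercept_sd,
                 bias_slope_mean = bias_slope_mean,
                 bias_slope_sd = bias_slope_sd,
                 noise_sd_test = noise_sd_test,
                 noise_sd_reference = noise_sd_reference,
                 test_dropout_prob = test_dropout_prob,
                 reference_dropout_prob = reference_dropout_prob),
            class = "device_error_model")
}

#' Synthetic cohort scenario
#'
#' Study conditions for the generator: a validation session of 3-6 continuous
#' hours with both devices worn, followed by a month of test-device-only
#' free-living wear with day-level compliance decaying geometrically. All
#' randomness is driven by `seed`; each participant and device uses its own
#' derived sub-seed, so adding a participant never perturbs the others' data.
#'
#' @param n_participants cohort size (default 10).
#' @param seed master integer seed.
#' @param age_mean,age_sd,age_range age sampling (years), truncated normal.
#' @param session_hours validation-session duration range in hours.
#' @param followup_days length of the free-living follow-up (0 to skip).
#' @param wear_prob day-1 probability that a participant wears the device.
#' @param compliance_decay per-day hazard of non-compliance: the wear
#'   probability on day d is `wear_prob * (1 - compliance_decay)^(d-1)`.
#' @param day_wear_minutes_mean,day_wear_minutes_sd daily wear-window length
#'   (minutes), normal, clamped to \[300, 1380\].
#' @param rest_hr_mean,rest_hr_sd,rest_hr_range resting-heart-rate sampling
#'   (bpm), truncated normal; a plausible adult range, not an estimate.
#' @param rest_multiplier range of the rest-state target as a multiple of
#'   resting heart rate.
#' @param hr_time_constant_s mean-reversion time constant of the true
#'   heart-rate process (s); state transitions are smoothed on this scale,
#'   emulating heart-rate lag after activity changes.
#' @param hr_process_sd per-second innovation SD of the true heart-rate
#'   process (bpm).
#' @param states an [activity_states()] model.
#' @param transitions 4×4 transition-probability matrix between states.
#' @param error_model a [device_error_model()].
#' @return A list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_participants = 10, seed = 1,
                            age_mean = 25.4, age_sd = 3.7, age_range = c(18, 65),
                            session_hours = c(3, 6), followup_days = 30,
                            wear_prob = 0.97, compliance_decay = 0.015,
                            day_wear_minutes_mean = 1150, day_wear_minutes_sd = 150,
                            rest_hr_mean = 65, rest_hr_sd = 6, rest_hr_range = c(50, 85),
                            rest_multiplier = c(1.00, 1.06),
                            hr_time_constant_s = 30, hr_process_sd = 0.6,
                            states = activity_states(),
                            transitions = default_transitions(),
                            error_model = device_error_model()) {
  stopifnot(n_participants >= 1, followup_days >= 0,
            session_hours[1] <= session_hours[2])
  structure(list(n_participants = as.integer(n_participants), seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 session_hours = session_hours, followup_days = as.integer(followup_days),
                 wear_prob = wear_prob, compliance_decay = compliance_decay,
                 day_wear_minutes_mean = day_wear_minutes_mean,
                 day_wear_minutes_sd = day_wear_minutes_sd,
                 rest_hr_mean = rest_hr_mean, rest_hr_sd = rest_hr_sd,
                 rest_hr_range = rest_hr_range, rest_multiplier = rest_multiplier,
                 hr_time_constant_s = hr_time_constant_s, hr_process_sd = hr_process_sd,
                 states = states, transitions = transitions, error_model = error_model),
            class = "cohort_scenario")
}

# Deterministic sub-seed derivation: participant index i, stream id k.
sub_seed <- function(seed, i, k) {
  as.integer((as.numeric(seed) + 1000003 * i + 97 * k) %% 2147483647L)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a true heart-rate trajectory
#'
#' Semi-Markov activity states with exponential dwell times; within each
#' bout the per-second true heart rate follows a mean-reverting AR(1)
#' process around the bout's target, so state transitions are smoothed over
#' roughly one minute (heart-rate lag). During nonwear the underlying
#' process continues (the person still has a heart rate) but no reading is
#' emitted by either observation model.
#'
#' @param age_years participant age.
#' @param rest_hr resting heart rate in bpm.
#' @param scenario a [cohort_scenario()].
#' @param duration_min trajectory length in whole minutes (>= 1).
#' @param seed integer seed for this trajectory.
#' @param start_state initial activity state (default `"rest"`).
#' @return A list of class `hr_truth`: `hr` (per-second true heart rate),
#'   `state` (per-second state label), `target` (per-second target),
#'   `duration_min`.
#' @export
simulate_truth <- function(age_years, rest_hr, scenario, duration_min,
                           seed, start_state = "rest") {
  stopifnot(duration_min >= 1)
  set.seed(seed)
  total_s <- as.integer(duration_min) * 60L
  st <- scenario$states
  P <- scenario$transitions
  max_hr <- max_heart_rate(age_years)
  draw_target <- function(state) {
    switch(state,
           rest = ,
           nonwear = rest_hr * stats::runif(1, scenario$rest_multiplier[1],
                                            scenario$rest_multiplier[2]),
           light = max_hr * stats::runif(1, st$intensity_lo["light"], st$intensity_hi["light"]),
           mvpa = max_hr * stats::runif(1, st$intensity_lo["mvpa"], st$intensity_hi["mvpa"]))
  }
  state_vec <- character(total_s)
  target_vec <- numeric(total_s)
  pos <- 0L
  cur <- start_state
  while (pos < total_s) {
    dwell_s <- max(30L, as.integer(round(stats::rexp(1, 1 / (st$dwell_min[cur] * 60)))))
    take <- min(dwell_s, total_s - pos)
    idx <- (pos + 1L):(pos + take)
    state_vec[idx] <- cur
    target_vec[idx] <- draw_target(cur)
    pos <- pos + take
    cur <- sample(colnames(P), 1L, prob = P[cur, ])
  }
  alpha <- 1 / scenario$hr_time_constant_s
  innov <- alpha * target_vec + stats::rnorm(total_s, 0, scenario$hr_process_sd)
  hr <- as.numeric(stats::filter(innov, 1 - alpha, method = "recursive",
                                 init = target_vec[1L]))
  structure(list(hr = hr, state = state_vec, target = target_vec,
                 duration_min = as.integer(duration_min)),
            class = "hr_truth")
}

#' Observe a truth trajectory with the 10-s reference device
#'
#' Samples the true heart rate every 10 s (offsets 0, 10, 20, ... within the
#' trajectory), adds reference noise, rounds to integer bpm and floors at
#' 25 bpm. Nonwear seconds and random dropouts emit 0.
#'
#' @param truth an `hr_truth` from [simulate_truth()].
#' @param participant_id,age_years identity of the wearer.
#' @param error_model a [device_error_model()].
#' @param seed integer seed for noise and dropout.
#' @param start_time POSIXct stream start (minute-aligned recommended).
#' @return A `reference` [sensor_stream()].
#' @export
observe_reference <- function(truth, participant_id, age_years, error_model,
                              seed, start_time) {
  set.seed(seed)
  total_s <- length(truth$hr)
  off <- seq(0L, total_s - 1L, by = 10L)
  val <- truth$hr[off + 1L] + stats::rnorm(length(off), 0, error_model$noise_sd_reference)
  val <- pmax(25, round(val))
  zero <- truth$state[off + 1L] == "nonwear" |
    stats::runif(length(off)) < error_model$reference_dropout_prob
  val[zero] <- 0
  sensor_stream(participant_id, age_years, "reference",
                start_time + off, as.integer(val))
}

#' Observe a truth trajectory with the 1-min test device
#'
#' For each clock minute the device averages the true heart rate over worn
#' seconds, applies the participant's error `b0 + b1 * max(0, mean - rest)`,
#' adds test noise, rounds and floors at 25 bpm. A minute that is mostly
#' nonwear (fewer than 30 worn seconds) or hit by dropout emits 0.
#'
#' @param truth an `hr_truth`.
#' @param participant_id,age_years identity of the wearer.
#' @param beta0,beta1 participant bias intercept (bpm) and intensity slope.
#' @param rest_hr participant resting heart rate (bpm).
#' @param error_model a [device_error_model()].
#' @param seed integer seed.
#' @param start_time POSIXct stream start; minute-aligned so that device
#'   minutes coincide with clock minutes.
#' @return A `test` [sensor_stream()].
#' @export
observe_test <- function(truth, participant_id, age_years, beta0, beta1,
                         rest_hr, error_model, seed, start_time) {
  set.seed(seed)
  nmin <- truth$duration_min
  m <- matrix(truth$hr, nrow = 60L)
  worn <- matrix(truth$state != "nonwear", nrow = 60L)
  worn_n <- colSums(worn)
  tm <- ifelse(worn_n > 0L, colSums(m * worn) / pmax(worn_n, 1L), NA_real_)
  biased <- tm + beta0 + beta1 * pmax(0, tm - rest_hr) +
    stats::rnorm(nmin, 0, error_model$noise_sd_test)
  val <- pmax(25, round(biased))
  zero <- worn_n < 30L | stats::runif(nmin) < error_model$test_dropout_prob
  val[zero | is.na(val)] <- 0
  sensor_stream(participant_id, age_years, "test",
                start_time + (seq_len(nmin) - 1L) * 60L, as.integer(val))
}

#' Simulate a full synthetic validation + free-living cohort
#'
#' For each participant: demographic and device-error parameters drawn from
#' the scenario's distributions; one validation session (3-6 h, both
#' devices); and `followup_days` of free-living test-only wear with
#' geometrically decaying day-level compliance. The generating parameters
#' (age, resting HR, bias intercept and slope) are retained as ground truth
#' for recovery tests.
#'
#' @param scenario a [cohort_scenario()].
#' @return A list of class `hr_cohort`: `participants` (registry data
#'   frame), `validation` (per participant: list with `test` and `reference`
#'   streams), `freeliving` (per participant: test stream or NULL),
#'   `truth` (data frame with `participant_id`, `age_years`, `rest_hr`,
#'   `beta0`, `beta1`), and `scenario`.
#' @export
simulate_cohort <- function(scenario = cohort_scenario()) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  em <- scenario$error_model
  n <- scenario$n_participants
  base_date <- as.POSIXct("2024-03-04T00:00:00", format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ids <- sprintf("P%02d", seq_len(n))
  validation <- vector("list", n); names(validation) <- ids
  freeliving <- vector("list", n); names(freeliving) <- ids
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seed(scenario$seed, i, 1L))
    age <- round(rnorm_trunc(1, scenario$age_mean, scenario$age_sd,
                             scenario$age_range[1], scenario$age_range[2]))
    rest <- rnorm_trunc(1, scenario$rest_hr_mean, scenario$rest_hr_sd,
                        scenario$rest_hr_range[1], scenario$rest_hr_range[2])
    beta0 <- stats::rnorm(1, em$bias_intercept_mean, em$bias_intercept_sd)
    beta1 <- stats::rnorm(1, em$bias_slope_mean, em$bias_slope_sd)
    dur_min <- as.integer(round(stats::runif(1, scenario$session_hours[1] * 60,
                                             scenario$session_hours[2] * 60)))
    start_min <- 9L * 60L + sample.int(180L, 1L) - 1L
    session_start <- base_date + start_min * 60L
    tr <- simulate_truth(age, rest, scenario, dur_min, sub_seed(scenario$seed, i, 2L))
    validation[[i]] <- list(
      test = observe_test(tr, ids[i], age, beta0, beta1, rest, em,
                          sub_seed(scenario$seed, i, 3L), session_start),
      reference = observe_reference(tr, ids[i], age, em,
                                    sub_seed(scenario$seed, i, 4L), session_start))
    if (scenario$followup_days > 0L) {
      ts_all <- list(); hr_all <- list()
      for (d in seq_len(scenario$followup_days)) {
        set.seed(sub_seed(scenario$seed, i, 10L + d))
        p_wear <- scenario$wear_prob * (1 - scenario$compliance_decay)^(d - 1)
        if (stats::runif(1) >= p_wear) next
        dmin <- as.integer(round(min(1380, max(300,
          stats::rnorm(1, scenario$day_wear_minutes_mean, scenario$day_wear_minutes_sd)))))
        day_start_min <- 6L * 60L + sample.int(120L, 1L) - 1L
        dmin <- min(dmin, 1440L - day_start_min)  # keep the window inside the day
        day_start <- base_date + (d * 86400L) + day_start_min * 60L
        trd <- simulate_truth(age, rest, scenario, dmin,
                              sub_seed(scenario$seed, i, 2000L + d))
        s <- observe_test(trd, ids[i], age, beta0, beta1, rest, em,
                          sub_seed(scenario$seed, i, 4000L + d), day_start)
        ts_all[[length(ts_all) + 1L]] <- s$samples$timestamp
        hr_all[[length(hr_all) + 1L]] <- s$samples$hr_bpm
      }
      if (length(ts_all) > 0L) {
        freeliving[[i]] <- sensor_stream(
          ids[i], age, "test",
          do.call(c, ts_all), unlist(hr_all))
      }
    }
    truth_rows[[i]] <- data.frame(participant_id = ids[i], age_years = age,
                                  rest_hr = rest, beta0 = beta0, beta1 = beta1,
                                  stringsAsFactors = FALSE)
  }
  ages <- vapply(truth_rows, function(r) r$age_years, numeric(1))
  structure(list(
    participants = participants(ids, ages, LETTERS[seq_len(n)]),
    validation = validation,
    freeliving = freeliving,
    truth = do.call(rbind, truth_rows),
    scenario = scenario), class = "hr_cohort")
}

#' @export
print.hr_cohort <- function(x, ...) {
  cat(sprintf("<hr_cohort> %d participants, seed %d; validation sessions: %d; free-living streams: %d\n",
              nrow(x$participants), x$scenario$seed,
              sum(!vapply(x$validation, is.null, logical(1))),
              sum(!vapply(x$freeliving, is.null, logical(1)))))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `participants.csv`, per-participant validation stream files
#' (`validation_test_<id>.csv`, `validation_reference_<id>.csv`),
#' free-living test streams (`freeliving_test_<id>.csv`), and the generating
#' ground truth as `truth.json`.
#'
#' @param cohort an `hr_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in cohort$participants$participant_id) {
    v <- cohort$validation[[id]]
    if (!is.null(v)) {
      write_stream(v$test, file.path(dir, sprintf("validation_test_%s.csv", id)))
      write_stream(v$reference, file.path(dir, sprintf("validation_reference_%s.csv", id)))
    }
    f <- cohort$freeliving[[id]]
    if (!is.null(f)) {
      write_stream(f, file.path(dir, sprintf("freeliving_test_%s.csv", id)))
    }
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing the CSV files.
#' @return An `hr_cohort`-like list (without `scenario`; `truth` only if
#'   `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  reg <- read_participants(file.path(dir, "participants.csv"))
  ids <- reg$participant_id
  validation <- lapply(ids, function(id) {
    tf <- file.path(dir, sprintf("validation_test_%s.csv", id))
    rf <- file.path(dir, sprintf("validation_reference_%s.csv", id))
    if (!file.exists(tf) && !file.exists(rf)) return(NULL)
    list(test = if (file.exists(tf)) read_stream(tf, "test", reg) else NULL,
         reference = if (file.exists(rf)) read_stream(rf, "reference", reg) else NULL)
  })
  names(validation) <- ids
  freeliving <- lapply(ids, function(id) {
    f <- file.path(dir, sprintf("freeliving_test_%s.csv", id))
    if (file.exists(f)) read_stream(f, "test", reg) else NULL
  })
  names(freeliving) <- ids
  tf <- file.path(dir, "truth.json")
  truth <- if (file.exists(tf)) as.data.frame(jsonlite::read_json(tf, simplifyVector = TRUE)) else NULL
  structure(list(participants = reg, validation = validation,
                 freeliving = freeliving, truth = truth, scenario = NULL),
            class = "hr_cohort")
}
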