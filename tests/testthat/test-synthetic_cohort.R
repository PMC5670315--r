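scenario_fast <- function(...) cohort_scenario(n_participants = 2, followup_days = 0, seed = 11, ...)

test_that("trajectories and cohorts are bit-reproducible under a fixed seed", {
  sc <- scenario_fast()
  t1 <- simulate_truth(25, 64, sc, 120, seed = 5)
  t2 <- simulate_truth(25, 64, sc, 120, seed = 5)
  expect_identical(t1$hr, t2$hr)
  expect_identical(t1$state, t2$state)

  c1 <- simulate_cohort(sc)
  c2 <- simulate_cohort(sc)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$validation$P01$test$samples, c2$validation$P01$test$samples)
  expect_identical(c1$validation$P02$reference$samples, c2$validation$P02$reference$samples)
})

test_that("adding a participant never perturbs existing participants' data", {
  c3 <- simulate_cohort(cohort_scenario(n_participants = 3, followup_days = 2, seed = 11))
  c4 <- simulate_cohort(cohort_scenario(n_participants = 4, followup_days = 2, seed = 11))
  for (id in c("P01", "P02", "P03")) {
    expect_identical(c3$validation[[id]]$test$samples, c4$validation[[id]]$test$samples)
    expect_identical(c3$freeliving[[id]]$samples, c4$freeliving[[id]]$samples)
  }
})

test_that("a rest-only model keeps the true heart rate in the rest band", {
  sc <- cohort_scenario(seed = 1)
  P <- matrix(0, 4, 4, dimnames = dimnames(sc$transitions))
  P["rest", "rest"] <- 1  # force rest as absorbing
  sc_rest <- cohort_scenario(seed = 1, transitions = P)
  tr <- simulate_truth(25, 65, sc_rest, 180, seed = 9, start_state = "rest")
  expect_true(all(tr$state == "rest"))
  # targets lie in rest_hr * [1.00, 1.06]; process sd ~2.3 bpm around them
  expect_true(all(tr$hr > 65 * 1.00 - 12 & tr$hr < 65 * 1.06 + 12))
  expect_lt(abs(mean(tr$hr) - 65 * 1.03), 3)
})

test_that("noise-free, dropout-free observation reproduces rounded truth", {
  em0 <- device_error_model(noise_sd_test = 0, noise_sd_reference = 0,
                            test_dropout_prob = 0, reference_dropout_prob = 0,
                            bias_intercept_sd = 0, bias_slope_sd = 0)
  sc <- cohort_scenario(seed = 2, error_model = em0)
  tr <- simulate_truth(25, 65, sc, 60, seed = 3)
  ref <- observe_reference(tr, "P01", 25, em0, seed = 4, start_time = t0())
  worn <- tr$state[seq(1, length(tr$hr), by = 10)] != "nonwear"
  expect_equal(ref$samples$hr_bpm[worn],
               as.integer(pmax(25, round(tr$hr[seq(1, length(tr$hr), by = 10)][worn]))))
  expect_true(all(ref$samples$hr_bpm[!worn] == 0L))

  # zero-bias test device equals the per-minute truth mean over worn seconds
  tst <- observe_test(tr, "P01", 25, beta0 = 0, beta1 = 0, rest_hr = 65,
                      em0, seed = 5, start_time = t0())
  m <- matrix(tr$hr, nrow = 60)
  w <- matrix(tr$state != "nonwear", nrow = 60)
  expected <- ifelse(colSums(w) >= 30, pmax(25, round(colSums(m * w) / pmax(colSums(w), 1))), 0)
  expect_equal(tst$samples$hr_bpm, as.integer(expected))
})

test_that("expected test bias at fixed intensity follows beta0 + beta1 * excess", {
  # beta0 = -4, beta1 = -0.15, 80 bpm above rest -> expected bias -16
  expect_equal(-4 + -0.15 * 80, -16)
  em0 <- device_error_model(noise_sd_test = 0, noise_sd_reference = 0,
                            test_dropout_prob = 0, reference_dropout_prob = 0)
  # constant-truth check through the observation model
  tr <- structure(list(hr = rep(145, 60 * 5), state = rep("rest", 60 * 5),
                       target = rep(145, 60 * 5), duration_min = 5L),
                  class = "hr_truth")
  tst <- observe_test(tr, "P01", 25, beta0 = -4, beta1 = -0.15, rest_hr = 65,
                      em0, seed = 1, start_time = t0())
  expect_true(all(tst$samples$hr_bpm == 145 - 16))
})

test_that("reference dropout rate matches its binomial expectation", {
  em <- device_error_model(reference_dropout_prob = 0.1, noise_sd_reference = 0)
  sc <- cohort_scenario(seed = 3, error_model = em)
  P <- matrix(0, 4, 4, dimnames = dimnames(sc$transitions))
  P["rest", "rest"] <- 1
  sc <- cohort_scenario(seed = 3, error_model = em, transitions = P)
  tr <- simulate_truth(30, 60, sc, 2000, seed = 7)  # 12000 10-s samples, all worn
  ref <- observe_reference(tr, "P01", 30, em, seed = 8, start_time = t0())
  n <- nrow(ref$samples)
  frac0 <- mean(ref$samples$hr_bpm == 0L)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac0 - 0.1), 3 * se)
})

test_that("long-run state occupancy matches the semi-Markov stationary distribution", {
  sc <- cohort_scenario(seed = 4)
  theo <- oracle_state_occupancy(sc$transitions,
                                 sc$states$dwell_min[colnames(sc$transitions)] * 60)
  reps <- 40
  burn_s <- 3600L  # discard the first hour: runs start deterministically at rest
  occ <- matrix(0, reps, 4, dimnames = list(NULL, colnames(sc$transitions)))
  for (r in 1:reps) {
    tr <- simulate_truth(25, 65, sc, 420, seed = 5000 + r)
    st <- tr$state[-seq_len(burn_s)]
    tab <- table(factor(st, levels = colnames(sc$transitions)))
    occ[r, ] <- as.numeric(tab) / length(st)
  }
  for (s in colnames(occ)) {
    mc_se <- sd(occ[, s]) / sqrt(reps)
    expect_lt(abs(mean(occ[, s]) - theo[colnames(occ) == s]), 3 * mc_se + 0.01)
  }
})

test_that("per-participant mean differences recover the generating bias parameters", {
  coh <- default_validation_cohort()
  for (i in seq_len(nrow(coh$truth))) {
    tr <- coh$truth[i, ]
    v <- coh$validation[[tr$participant_id]]
    p <- pair_streams(v$test, v$reference)
    # subtract the known intensity-slope term to isolate beta0
    adj <- p$difference_bpm - tr$beta1 * pmax(0, p$reference_mean_bpm - tr$rest_hr)
    se <- sd(adj) / sqrt(length(adj))
    expect_lt(abs(mean(adj) - tr$beta0), 3 * se + 0.3)
  }
})

test_that("zero compliance decay yields a full month of valid days", {
  sc <- cohort_scenario(n_participants = 2, followup_days = 6, seed = 13,
                        wear_prob = 1, compliance_decay = 0,
                        day_wear_minutes_mean = 1150, day_wear_minutes_sd = 0)
  coh <- simulate_cohort(sc)
  for (id in c("P01", "P02")) {
    d <- daily_wear_summaries(coh$freeliving[[id]])
    expect_equal(sum(d$is_valid_day), 6L)
  }
})

test_that("default compliance decay produces a non-increasing adherence trend", {
  coh <- simulate_cohort(cohort_scenario(n_participants = 6, followup_days = 20, seed = 17))
  days <- do.call(rbind, lapply(Filter(Negate(is.null), coh$freeliving),
                                daily_wear_summaries))
  a <- adherence_curve(days)
  # trend, not strict monotonicity: first third vs last third of follow-up
  k <- nrow(a)
  expect_gte(mean(a$n_valid[1:floor(k / 3)]), mean(a$n_valid[(k - floor(k / 3) + 1):k]))
})

test_that("cohort files round-trip through write_cohort/read_cohort", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(cohort_scenario(n_participants = 2, followup_days = 2, seed = 19))
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$participants$participant_id, coh$participants$participant_id)
  expect_identical(back$validation$P01$test$samples$hr_bpm,
                   coh$validation$P01$test$samples$hr_bpm)
  expect_identical(back$freeliving$P02$samples$hr_bpm, coh$freeliving$P02$samples$hr_bpm)
  expect_equal(back$truth$beta0, coh$truth$beta0, tolerance = 1e-12)
})
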