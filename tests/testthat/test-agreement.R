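test_that("mean difference matches direct arithmetic on a hand-computed fixture", {
  d <- c(-4, -6, -5, -7, -3)
  md <- mean_difference(d)
  expect_equal(md$mean_diff_bpm, -5)
  expect_equal(md$se_bpm, sd(d) / sqrt(5))
  expect_equal(md$t_statistic, -5 / (sd(d) / sqrt(5)))
  expect_equal(md$ci95[1], -5 - qt(0.975, 4) * sd(d) / sqrt(5))
  expect_equal(md$ci95[2], -5 + qt(0.975, 4) * sd(d) / sqrt(5))
  expect_equal(md$p_value, 2 * pt(-abs(md$t_statistic), 4))
})

test_that("constant differences are degenerate: se 0, t and p undefined", {
  md <- mean_difference(c(-5, -5, -5, -5))
  expect_equal(md$mean_diff_bpm, -5)
  expect_equal(md$se_bpm, 0)
  expect_true(md$degenerate)
  expect_true(is.na(md$t_statistic))
  expect_true(is.na(md$p_value))
  expect_equal(md$ci95, c(-5, -5))

  md0 <- mean_difference(rep(0, 6))
  expect_equal(md0$mean_diff_bpm, 0)
  expect_true(is.na(md0$t_statistic))

  expect_error(mean_difference(numeric(1)), "at least 2")
})

test_that("icc_a1 matches the brute-force ANOVA oracle on a fixed integer table", {
  M <- matrix(c(7, 9, 4, 6, 8, 2,
                6, 8, 5, 7, 9, 3), ncol = 2)
  expect_equal(icc_a1(M)$icc, oracle_icc_a1(M), tolerance = 1e-12)
})

test_that("icc_a1 agrees with the sums-of-squares oracle on many random small tables", {
  set.seed(2024)
  for (rep in 1:250) {
    n <- sample(3:20, 1)
    base <- runif(n, 50, 180)
    M <- cbind(base + rnorm(n, 0, runif(1, 0.5, 15)),
               base + rnorm(n, sample(-15:5, 1), runif(1, 0.5, 15)))
    if (max(M) == min(M)) next
    expect_equal(icc_a1(M)$icc, oracle_icc_a1(M), tolerance = 1e-10)
  }
})

test_that("perfect agreement gives ICC 1; constant offsets lower absolute agreement", {
  base <- c(60, 80, 100, 120, 150, 180)
  expect_equal(icc_a1(cbind(base, base))$icc, 1)

  # constant -10 bpm offset: absolute agreement < 1 and < consistency ICC
  M <- cbind(base - 10, base)
  r <- icc_a1(M)
  expect_lt(r$icc, 1)
  # consistency-form ICC on the same data (offset invisible to it)
  n <- nrow(M)
  rm_ <- rowMeans(M); cm_ <- colMeans(M); gm <- mean(M)
  msr <- 2 * sum((rm_ - gm)^2) / (n - 1)
  mse <- sum((M - outer(rm_, c(1, 1)) - outer(rep(1, n), cm_) + gm)^2) / (n - 1)
  icc_consistency <- (msr - mse) / (msr + mse)
  expect_lt(r$icc, icc_consistency)

  expect_error(icc_a1(cbind(rep(5, 4), rep(5, 4))), "zero total variance")
})

test_that("adding a constant offset to one device never increases ICC(A,1)", {
  # ICC(A,1) is a decreasing function of the absolute between-device mean
  # gap (row and error mean squares are offset-invariant), so starting from
  # mean-matched devices any constant offset can only lower it.
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    base <- runif(n, 60, 170)
    M <- cbind(base + rnorm(n, 0, 5), base + rnorm(n, 0, 5))
    M[, 1] <- M[, 1] - mean(M[, 1]) + mean(M[, 2])
    r0 <- icc_a1(M)$icc
    for (off in c(-15, -2, 2, 5, 15, 40)) {
      M2 <- M; M2[, 1] <- M2[, 1] + off
      expect_lte(icc_a1(M2)$icc, r0 + 1e-12)
    }
  }
})

test_that("icc confidence interval brackets the estimate and matches hand formula", {
  set.seed(3)
  base <- runif(30, 60, 160)
  M <- cbind(base + rnorm(30, -5, 6), base + rnorm(30, 0, 2))
  r <- icc_a1(M)
  expect_lte(r$ci95[1], r$icc)
  expect_gte(r$ci95[2], r$icc)
  expect_true(r$ci95[1] < r$ci95[2])
})

test_that("icc strength labels: weak below .5, strong above .7, closed [.5,.7] moderate", {
  expect_equal(icc_strength(0.83), "strong")
  expect_equal(icc_strength(0.71), "strong")
  expect_equal(icc_strength(0.7), "moderate")
  expect_equal(icc_strength(0.5), "moderate")
  expect_equal(icc_strength(0.49), "weak")
  expect_equal(icc_strength(-0.2), "weak")
})

test_that("bland-altman bias and limits match direct arithmetic", {
  # constant differences: zero-width limits
  ba <- bland_altman(list(test = c(75, 95, 115), reference = c(80, 100, 120)))
  expect_equal(ba$bias_bpm, -5)
  expect_equal(ba$loa_lower_bpm, -5)
  expect_equal(ba$loa_upper_bpm, -5)

  # symmetric differences with known sd
  d <- c(-2, 2, -2, 2)
  ba2 <- bland_altman(list(test = 100 + d, reference = rep(100, 4)))
  expect_equal(ba2$bias_bpm, 0)
  expect_equal(ba2$loa_upper_bpm, 1.96 * sd(d))

  # 10-pair fixture vs hand computation
  set.seed(8)
  ref <- round(runif(10, 70, 150))
  tst <- round(ref - 6 + rnorm(10, 0, 4))
  ba3 <- bland_altman(list(test = tst, reference = ref))
  expect_equal(ba3$bias_bpm, mean(tst - ref))
  expect_equal(ba3$sd_diff_bpm, sd(tst - ref))
  expect_equal(ba3$loa_lower_bpm, mean(tst - ref) - 1.96 * sd(tst - ref))
  expect_equal(ba3$points$mean_bpm, (tst + ref) / 2)
  expect_error(bland_altman(list(test = 1, reference = 1)), "at least 2")
})

test_that("a single all-encompassing stratum reproduces the unstratified results", {
  pairs <- cohort_pairs(default_validation_cohort())
  s <- stratified_agreement(pairs, rep("all", nrow(pairs)))
  expect_equal(s$all$mean_difference$mean_diff_bpm, mean_difference(pairs)$mean_diff_bpm)
  expect_equal(s$all$icc$icc, icc_a1(pairs)$icc)
  expect_equal(s$all$bland_altman$loa_lower_bpm, bland_altman(pairs)$loa_lower_bpm)
})

test_that("pooling stratified partitions reproduces the unstratified computation", {
  pairs <- cohort_pairs(default_validation_cohort())
  parts <- split(seq_len(nrow(pairs)), pairs$participant_id)
  pooled <- pool_pairs(lapply(parts, function(i) pairs[i, , drop = FALSE]))
  expect_equal(icc_a1(pooled)$icc, icc_a1(pairs)$icc, tolerance = 1e-12)
  expect_equal(mean_difference(pooled)$mean_diff_bpm,
               mean_difference(pairs)$mean_diff_bpm, tolerance = 1e-12)
})

test_that("undersized strata are flagged insufficient, never dropped", {
  pairs <- cohort_pairs(default_validation_cohort())[1:5, ]
  lab <- c("a", "a", "a", "a", "b")   # stratum b has a single pair
  s <- stratified_agreement(pairs, lab)
  expect_named(s, c("a", "b"))
  expect_equal(s$b$n, 1L)
  expect_true("mean_difference" %in% s$b$insufficient)
  expect_true("icc" %in% s$b$insufficient)
  expect_null(s$b$icc)
  expect_error(stratified_agreement(pairs, lab[1:3]), "match")
})

test_that("decile ranking partitions pairs into near-equal rank-ordered groups", {
  mk_pairs <- function(ref, tst) {
    structure(data.frame(participant_id = "P01", age_years = 25,
                         start = t0() + seq_along(ref) * 60,
                         test_bpm = tst, reference_mean_bpm = ref,
                         reference_range_width_bpm = 0,
                         difference_bpm = tst - ref),
              class = c("paired_epochs", "data.frame"))
  }
  d <- decile_summary(mk_pairs(26:45, 26:45 - 5))
  expect_equal(d$n, rep(2L, 10))
  expect_equal(d$ref_lo[1], 26); expect_equal(d$ref_hi[1], 27)
  expect_equal(d$ref_lo[10], 44); expect_equal(d$ref_hi[10], 45)

  # all-identical values collapse every five-number summary
  di <- decile_summary(mk_pairs(rep(80, 12), rep(80, 12)))
  expect_true(all(di$ref_min == 80 & di$ref_max == 80 & di$test_med == 80))
  # group sizes differ by at most one
  expect_true(max(di$n) - min(di$n) <= 1)
  expect_error(decile_summary(mk_pairs(1:9 + 25, 1:9 + 25)), "at least 10")
})

test_that("synthetic cohort: test medians fall below reference medians in upper deciles", {
  pairs <- cohort_pairs(default_validation_cohort())
  d <- decile_summary(pairs)
  expect_true(all(d$test_med[8:10] < d$ref_med[8:10]))
})
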