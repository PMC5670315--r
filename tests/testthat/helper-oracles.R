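# Independent oracles, deliberately written with naive explicit loops so they
# share no code with the package implementation.

# Brute-force two-way ANOVA ICC(A,1): explicit double-loop sums of squares.
oracle_icc_a1 <- function(M) {
  n <- nrow(M); k <- ncol(M)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + M[i, j]
  grand <- grand / (n * k)
  row_means <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in 1:k) s <- s + M[i, j]
    row_means[i] <- s / k
  }
  col_means <- numeric(k)
  for (j in 1:k) {
    s <- 0
    for (i in 1:n) s <- s + M[i, j]
    col_means[j] <- s / n
  }
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (row_means[i] - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (col_means[j] - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (M[i, j] - row_means[i] - col_means[j] + grand)^2
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Time-stationary state occupancy of the semi-Markov activity model:
# embedded-chain stationary distribution (left eigenvector) weighted by the
# effective mean dwell per state. Dwell times in the generator are
# exponential, rounded, and floored at 30 s; E[max(30, X)] = 30 + m*exp(-30/m)
# for X ~ Exp(mean m).
oracle_state_occupancy <- function(P, dwell_mean_s, floor_s = 30) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi_embedded <- Re(ev$vectors[, i])
  pi_embedded <- pi_embedded / sum(pi_embedded)
  eff_dwell <- floor_s + dwell_mean_s * exp(-floor_s / dwell_mean_s)
  occ <- pi_embedded * eff_dwell
  occ / sum(occ)
}
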