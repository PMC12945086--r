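# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own closed forms: the posterior oracle integrates the
# unnormalized density theta^a (1-theta)^(N-a) by composite Simpson
# quadrature, and the signed-rank oracle enumerates all 2^n sign patterns.

simpson_weights <- function(m) {
  stopifnot(m %% 2L == 1L, m >= 3L)
  w <- numeric(m)
  w[c(1L, m)] <- 1
  w[seq(2L, m - 1L, 2L)] <- 4
  if (m > 3L) w[seq(3L, m - 2L, 2L)] <- 2
  w
}

# Posterior over completion probability from counters (N, a), by quadrature.
# Returns normalized density values, the CDF on the grid, and the mean.
beta_posterior_oracle <- function(N, a, m = 20001L) {
  x <- seq(0, 1, length.out = m)
  f <- x^a * (1 - x)^(N - a)
  w <- simpson_weights(m)
  h <- 1 / (m - 1)
  Z <- sum(w * f) * h / 3
  mean <- sum(w * x * f) * h / 3 / Z
  # cumulative Simpson over consecutive point pairs (trapezoid refinement on
  # the half-steps would do; per-interval Simpson needs odd spans, so use
  # cumulative trapezoid on the fine grid — at m = 20001 its error is far
  # below the tolerances it is used at)
  cdf <- cumsum(c(0, (f[-1] + f[-m]) / 2 * h)) / Z
  cdf <- pmin(1, cdf / cdf[m])
  list(x = x, pdf = f / Z, cdf = cdf, mean = mean)
}

# P(theta_A > theta_B) by numeric double integration on a grid:
# integral f_A(x) * F_B(x) dx.
prob_a_beats_b_oracle <- function(NA_, aA, NB, aB, m = 20001L) {
  A <- beta_posterior_oracle(NA_, aA, m)
  B <- beta_posterior_oracle(NB, aB, m)
  w <- simpson_weights(m)
  h <- 1 / (m - 1)
  sum(w * A$pdf * B$cdf) * h / 3
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments of the tie-averaged ranks of |d| (zero differences removed
# by the caller). n <= ~16 only.
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1L, n <= 16L)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_le <- mean(W_all <= W_obs + 1e-9)
  p_ge <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Empirical KS distance between sorted draws and an oracle CDF given on a grid.
ks_distance <- function(draws, grid_x, grid_cdf) {
  s <- sort(draws)
  n <- length(s)
  Fhat <- stats::approx(grid_x, grid_cdf, xout = s, rule = 2)$y
  max(abs(Fhat - seq_len(n) / n), abs(Fhat - (seq_len(n) - 1) / n))
}

# Tiny hand-built study log: one user, explicit events.
tiny_log <- function(events, user_id = "u01", tz = "UTC") {
  study_log(users = list(list(user_id = user_id, seed = 1L)),
            events = events, tz = tz)
}
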