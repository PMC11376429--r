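# Independent numerical oracles and fixture builders shared across tests.

# Trapezoidal intersection-over-union of two Gaussian densities on a dense
# grid spanning both means +/- 8 sd, step sigma/1000. Independent of the
# package's closed-form path.
overlap_oracle <- function(mu1, s1, mu2, s2) {
  smax <- max(s1, s2)
  lo <- min(mu1, mu2) - 8 * smax
  hi <- max(mu1, mu2) + 8 * smax
  x <- seq(lo, hi, by = min(s1, s2) / 1000)
  f <- dnorm(x, mu1, s1)
  g <- dnorm(x, mu2, s2)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * (x[2] - x[1])
  inter <- trap(pmin(f, g))
  union <- trap(pmax(f, g))
  list(overlap = inter, union = union, probability = inter / union)
}

# Arc trajectory followed by a stationary tail, so the stop rule can fire.
stopped_trajectory <- function(midpoint_x = 0.03, duration = 1.6,
                               tail_s = 0.8, rate = 1000) {
  tr <- sample_trajectory(arc_path(midpoint_x), duration, rate = rate)
  n <- nrow(tr)
  tail_n <- round(tail_s * rate)
  tail_df <- data.frame(t_s = tr$t_s[n] + seq_len(tail_n) / rate,
                        x_m = tr$x_m[n], y_m = tr$y_m[n])
  out <- rbind(as.data.frame(tr), tail_df)
  attr(out, "sample_rate") <- rate
  class(out) <- c("trajectory", "data.frame")
  out
}

# Noise-free cohort: every report equals its generative mean.
noiseless_cohort <- function(n, w_static = NULL) {
  cohort <- make_cohort(n, seed = 99)
  cohort$sigma2_v <- cohort$sigma2_p <- 1e-12
  cohort$motor_noise <- 0
  cohort$bias_v <- cohort$bias_p <- 0
  cohort <- set_mle_weights(cohort, k = 0)
  if (!is.null(w_static))
    cohort$w_static_v <- cohort$w_static_p <- w_static
  cohort
}
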