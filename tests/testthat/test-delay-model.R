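vision <- sensory_channel("vision", 1e-4, 0.070)
prop <- sensory_channel("proprioception", 1e-4, 0.020)

test_that("delayed unimodal estimates lag the limb by speed times delay", {
  # stationary limb: delay irrelevant
  expect_equal(delayed_unimodal_mean(vision, motion_state(0, 1, 0.12)), 0.12)
  # no delay: current position
  nod <- sensory_channel("vision", 1e-4, 0)
  expect_equal(delayed_unimodal_mean(nod, motion_state(0.2, 1)), 0.2)
  # 70 ms delay at 0.2 m/s: position 14 mm behind
  expect_equal(delayed_unimodal_mean(vision, motion_state(0.2, 1)), 0.186)
  # cross-check by reading a constant-velocity path at t - tau
  path_pos <- function(t) 0.2 * t
  expect_equal(delayed_unimodal_mean(vision, motion_state(0.2, 1)),
               path_pos(1 - 0.070))
  # static bias adds through
  biased <- sensory_channel("proprioception", 1e-4, 0.02, static_bias = 0.01)
  expect_equal(delayed_unimodal_mean(biased, motion_state(0.1, 0.5)),
               0.1 * 0.48 + 0.01)
})

test_that("reliability-weighted combination matches the likelihood-product optimum", {
  a <- gaussian_estimate(0, 1); b <- gaussian_estimate(1, 4)
  comb <- mle_combine(a, b)
  expect_equal(comb$mean, 0.2)
  expect_equal(comb$variance, 0.8)
  # independent oracle: grid-search mode of the product of the two likelihoods
  grid <- seq(-2, 3, by = 1e-4)
  ll <- dnorm(grid, 0, 1, log = TRUE) + dnorm(grid, 1, 2, log = TRUE)
  expect_equal(comb$mean, grid[which.max(ll)], tolerance = 1e-3)
  # symmetry and idempotent-mean cases
  s <- 2.5e-4
  sym <- mle_combine(gaussian_estimate(0, s), gaussian_estimate(1, s))
  expect_equal(sym$mean, 0.5)
  expect_equal(sym$variance, s / 2)
  self <- mle_combine(a, a)
  expect_equal(self$mean, a$mean)
  expect_equal(self$variance, a$variance / 2)
  expect_error(mle_combine(a, list(mean = 0, variance = -1)),
               class = "delaymle_invalid_parameter")
})

test_that("combined variance is strictly below both inputs", {
  set.seed(11)
  for (i in 1:50) {
    va <- runif(1, 1e-6, 1e-3); vb <- runif(1, 1e-6, 1e-3)
    comb <- mle_combine(gaussian_estimate(rnorm(1), va),
                        gaussian_estimate(rnorm(1), vb))
    expect_lt(comb$variance, min(va, vb))
  }
})

test_that("delay-induced bimodal offset is the reliability-weighted mean lag", {
  expect_equal(bimodal_offset_error(0, vision, prop), 0)
  # equal variances: simple mean of the delays
  expect_equal(bimodal_offset_error(0.187, vision, prop), 0.187 * 0.045)
  # equal delays: nu * tau regardless of variances
  v2 <- sensory_channel("vision", 3e-4, 0.05)
  p2 <- sensory_channel("proprioception", 9e-5, 0.05)
  expect_equal(bimodal_offset_error(0.3, v2, p2), 0.3 * 0.05)
  # composition check: offset equals ideal minus actual combined means
  speeds <- c(0.05, 0.187, 0.4)
  for (nu in speeds) {
    mv <- delayed_unimodal_mean(vision, motion_state(nu, 1))
    mp <- delayed_unimodal_mean(prop, motion_state(nu, 1))
    actual <- mle_combine(gaussian_estimate(mv, vision$variance),
                          gaussian_estimate(mp, prop$variance))
    ideal <- mle_combine(gaussian_estimate(nu * 1, vision$variance),
                         gaussian_estimate(nu * 1, prop$variance))
    expect_equal(ideal$mean - actual$mean,
                 bimodal_offset_error(nu, vision, prop))
  }
})

test_that("offset is linear in speed and bracketed by the two delays", {
  set.seed(21)
  for (i in 1:20) {
    v <- sensory_channel("vision", runif(1, 1e-6, 1e-3), runif(1, 0, 0.2))
    p <- sensory_channel("proprioception", runif(1, 1e-6, 1e-3),
                         runif(1, 0, 0.2))
    nu <- runif(1, 0.01, 0.5)
    off <- bimodal_offset_error(nu, v, p)
    expect_equal(off, nu * bimodal_offset_error(1, v, p))
    expect_gte(off, nu * min(v$delay, p$delay) - 1e-15)
    expect_lte(off, nu * max(v$delay, p$delay) + 1e-15)
  }
})

test_that("gaussian crossing sits between the means", {
  expect_equal(as.numeric(gaussian_crossing(gaussian_estimate(0, 4e-4),
                                            gaussian_estimate(1, 4e-4))), 0.5)
  # unequal variances: dense grid oracle for the between-means root
  a <- gaussian_estimate(0, 1); b <- gaussian_estimate(2, 4)
  cc <- gaussian_crossing(a, b)
  grid <- seq(0, 2, by = 1e-6)
  oracle <- grid[which.min(abs(dnorm(grid, 0, 1) - dnorm(grid, 2, 2)))]
  expect_equal(as.numeric(cc), oracle, tolerance = 1e-5)
  expect_false(attr(cc, "degenerate"))
  # identical distributions: degenerate, crossing at the mean
  dg <- gaussian_crossing(a, a)
  expect_true(attr(dg, "degenerate"))
  expect_equal(as.numeric(dg), a$mean)
  # argument order must not matter
  expect_equal(as.numeric(gaussian_crossing(b, a)), as.numeric(cc))
})

test_that("overlap probability has the right limits and closed form", {
  x <- gaussian_estimate(0.1, 1e-4)
  expect_equal(overlap_probability(x, x)$probability, 1, tolerance = 1e-12)
  # |dmu| = 2 sd: overlap 2*Phi(-1), probability ~ 0.18857
  o <- overlap_probability(gaussian_estimate(0, 1), gaussian_estimate(2, 1))
  expect_equal(o$overlap_area, 2 * pnorm(-1), tolerance = 1e-12)
  expect_equal(o$probability, 2 * pnorm(-1) / (2 - 2 * pnorm(-1)),
               tolerance = 1e-12)
  expect_equal(o$overlap_area + o$union_area, 2)
  # widely separated means: probability vanishes
  far <- overlap_probability(gaussian_estimate(0, 1e-4),
                             gaussian_estimate(1, 1e-4))
  expect_lt(far$probability, 1e-12)
})

test_that("overlap probability is symmetric and translation invariant", {
  set.seed(31)
  for (i in 1:20) {
    a <- gaussian_estimate(rnorm(1), runif(1, 1e-5, 1e-3))
    b <- gaussian_estimate(rnorm(1), runif(1, 1e-5, 1e-3))
    p1 <- overlap_probability(a, b)$probability
    expect_equal(overlap_probability(b, a)$probability, p1)
    shift <- rnorm(1)
    expect_equal(
      overlap_probability(gaussian_estimate(a$mean + shift, a$variance),
                          gaussian_estimate(b$mean + shift, b$variance))$probability,
      p1, tolerance = 1e-12)
    expect_gte(p1, 0); expect_lte(p1, 1)
  }
})

test_that("unequal-variance overlap matches the min/max density oracle", {
  # the between-means crossing rule coincides with the true min/max integral
  # whenever the outer crossing carries negligible mass
  a <- gaussian_estimate(0, 1)
  b <- gaussian_estimate(1.5, 1.2)
  got <- overlap_probability(a, b)
  want <- overlap_oracle(0, 1, 1.5, sqrt(1.2))
  expect_equal(got$probability, want$probability, tolerance = 1e-4)
})

test_that("sweep composes offset and overlap over full grids", {
  sw <- run_sweep(speed = c(0, 0.001, 0.187), tau_v = c(0.05, 0.07),
                  tau_p = 0.02, var_v = 1e-4, var_p = c(1e-4, 4e-4))
  expect_equal(nrow(sw), 3 * 2 * 2)
  expect_named(sw, c("speed_mps", "tau_v_s", "tau_p_s", "var_v_m2",
                     "var_p_m2", "offset_m", "probability"))
  # zero speed: probability exactly 1
  expect_true(all(sw$probability[sw$speed_mps == 0] == 1))
  # probability ordered descending in speed within each parameter family
  fam <- split(sw, interaction(sw$tau_v_s, sw$var_p_m2))
  for (f in fam) expect_true(all(diff(f$probability[order(f$speed_mps)]) <= 0))
  # each sweep row reproduces the two underlying operations
  r <- sw[sw$speed_mps == 0.187 & sw$tau_v_s == 0.07 & sw$var_p_m2 == 1e-4, ]
  v <- sensory_channel("vision", r$var_v_m2, r$tau_v_s)
  p <- sensory_channel("proprioception", r$var_p_m2, r$tau_p_s)
  expect_equal(r$offset_m, bimodal_offset_error(0.187, v, p))
  vb <- mle_combine(gaussian_estimate(0, r$var_v_m2),
                    gaussian_estimate(0, r$var_p_m2))$variance
  expect_equal(r$probability,
               overlap_probability(gaussian_estimate(-r$offset_m, vb),
                                   gaussian_estimate(0, vb))$probability)
  # halving both variances at fixed speed never increases the probability
  sw1 <- run_sweep(speed = 0.1, var_v = 1e-4, var_p = 1e-4)
  sw2 <- run_sweep(speed = 0.1, var_v = 5e-5, var_p = 5e-5)
  expect_lte(sw2$probability, sw1$probability)
  expect_error(run_sweep(speed = numeric(0)), class = "delaymle_invalid_grid")
  expect_error(run_sweep(speed = c(0.2, 0.1)), class = "delaymle_invalid_grid")
})
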