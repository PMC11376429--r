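#' Sensory feedback channel
#'
#' Describes one sensory modality's feedback about limb position: its report
#' variance, its feedback delay, and an optional constant spatial bias. Vision
#' and proprioception differ most importantly in delay: cortical feedback
#' latencies are roughly 70 ms for vision and 20 ms for proprioception, which
#' is what makes multisensory integration problematic while the limb moves.
#'
#' @param modality `"vision"` or `"proprioception"`.
#' @param variance Report variance in m^2; must be positive.
#' @param delay Feedback delay in seconds; must be non-negative.
#' @param static_bias Constant spatial bias in metres (default 0).
#' @return An object of class `"sensory_channel"`.
#' @examples
#' vision <- sensory_channel("vision", variance = 1e-4, delay = 0.070)
#' prop   <- sensory_channel("proprioception", variance = 1e-4, delay = 0.020)
#' @export
sensory_channel <- function(modality = c("vision", "proprioception"),
                            variance, delay, static_bias = 0) {
  modality <- match.arg(modality)
  if (!is_number(variance) || variance <= 0)
    stop_delaymle("'variance' must be a single positive number (m^2)",
                  "delaymle_invalid_parameter")
  if (!is_number(delay) || delay < 0)
    stop_delaymle("'delay' must be a single non-negative number (s)",
                  "delaymle_invalid_parameter")
  if (!is_number(static_bias))
    stop_delaymle("'static_bias' must be a single finite number (m)",
                  "delaymle_invalid_parameter")
  structure(list(modality = modality, variance = variance, delay = delay,
                 static_bias = static_bias),
            class = "sensory_channel")
}

#' @export
print.sensory_channel <- function(x, ...) {
  cat(sprintf("<sensory_channel> %s: variance %.3g m^2, delay %.3g s, bias %.3g m\n",
              x$modality, x$variance, x$delay, x$static_bias))
  invisible(x)
}

#' Instantaneous motion state of the limb
#'
#' A snapshot of a constant-velocity limb motion: the speed, the evaluation
#' time, and the position of the limb at the reference instant (time zero).
#' Signed speeds are permitted so that direction-of-motion effects can be
#' explored.
#'
#' @param speed Movement speed in m/s (may be signed).
#' @param time Evaluation time in seconds.
#' @param reference_position Limb position at time zero, in metres (default 0).
#' @return An object of class `"motion_state"`.
#' @export
motion_state <- function(speed, time, reference_position = 0) {
  if (!is_number(speed) || !is_number(time) || !is_number(reference_position))
    stop_delaymle("speed, time and reference_position must be single finite numbers",
                  "delaymle_invalid_parameter")
  structure(list(speed = speed, time = time,
                 reference_position = reference_position),
            class = "motion_state")
}

#' Gaussian position estimate
#'
#' A position belief expressed as a Gaussian with mean (m) and variance (m^2).
#'
#' @param mean Mean position in metres.
#' @param variance Variance in m^2; must be positive.
#' @return An object of class `"gaussian_estimate"`.
#' @export
gaussian_estimate <- function(mean, variance) {
  if (!is_number(mean))
    stop_delaymle("'mean' must be a single finite number (m)",
                  "delaymle_invalid_parameter")
  if (!is_number(variance) || variance <= 0)
    stop_delaymle("'variance' must be a single positive number (m^2)",
                  "delaymle_invalid_parameter")
  structure(list(mean = mean, variance = variance),
            class = "gaussian_estimate")
}

#' @export
print.gaussian_estimate <- function(x, ...) {
  cat(sprintf("<gaussian_estimate> N(mean = %.6g m, variance = %.6g m^2)\n",
              x$mean, x$variance))
  invisible(x)
}

#' Delayed unimodal position estimate
#'
#' The position a sensory channel reports at time `t` is the true position the
#' limb occupied `delay` seconds earlier. On a constant-velocity path this is
#' `reference_position + speed * (t - delay) + static_bias`: the estimate lags
#' the limb by `speed * delay` metres.
#'
#' @param channel A [sensory_channel()].
#' @param motion A [motion_state()].
#' @return The channel's reported position in metres (scalar).
#' @examples
#' v <- sensory_channel("vision", 1e-4, 0.070)
#' delayed_unimodal_mean(v, motion_state(speed = 0.2, time = 1)) # 0.186
#' @export
delayed_unimodal_mean <- function(channel, motion) {
  stopifnot(inherits(channel, "sensory_channel"),
            inherits(motion, "motion_state"))
  motion$reference_position +
    motion$speed * (motion$time - channel$delay) +
    channel$static_bias
}

#' Reliability-weighted (maximum-likelihood) combination of two estimates
#'
#' Combines two Gaussian position estimates by weighting each mean with the
#' other's variance: `mean = (var_b * mean_a + var_a * mean_b) / (var_a +
#' var_b)`, `variance = var_a * var_b / (var_a + var_b)`. The combined variance
#' is always strictly smaller than either input variance — the classical
#' benefit of multisensory integration.
#'
#' @param a,b [gaussian_estimate()] objects (or lists with `mean`, `variance`).
#' @return A [gaussian_estimate()] for the combined belief.
#' @examples
#' mle_combine(gaussian_estimate(0, 1), gaussian_estimate(1, 4)) # mean 0.2, var 0.8
#' @export
mle_combine <- function(a, b) {
  if (!is_number(a$variance) || a$variance <= 0 ||
      !is_number(b$variance) || b$variance <= 0)
    stop_delaymle("both variances must be positive", "delaymle_invalid_parameter")
  s <- a$variance + b$variance
  gaussian_estimate(mean = (b$variance * a$mean + a$variance * b$mean) / s,
                    variance = a$variance * b$variance / s)
}

#' Delay-induced offset of the bimodal state estimate
#'
#' When the limb moves at speed `v`, the reliability-weighted bimodal estimate
#' built from delayed feedback lags the ideal (zero-delay) bimodal estimate by
#' the reliability-weighted mean delay times the speed:
#' `v * (var_p * tau_v + var_v * tau_p) / (var_v + var_p)`.
#' This offset is the sole difference between the actual and ideal bimodal
#' estimate distributions (the variances are unchanged by delay).
#'
#' @param speed Movement speed in m/s (signed allowed).
#' @param vision,prop [sensory_channel()] objects for vision and
#'   proprioception.
#' @return Offset in metres (positive = actual estimate lags behind).
#' @examples
#' v <- sensory_channel("vision", 1e-4, 0.070)
#' p <- sensory_channel("proprioception", 1e-4, 0.020)
#' bimodal_offset_error(0.187, v, p) # 0.187 * 0.045 = 0.008415 m
#' @export
bimodal_offset_error <- function(speed, vision, prop) {
  stopifnot(inherits(vision, "sensory_channel"),
            inherits(prop, "sensory_channel"))
  s <- vision$variance + prop$variance
  speed * (prop$variance * vision$delay + vision$variance * prop$delay) / s
}

#' Crossing point of two Gaussian densities
#'
#' Finds the point `c` between the two means at which the two densities are
#' equal. With equal variances this is the midpoint of the means; with unequal
#' variances it is the between-means root of the log-density equality (the
#' outer crossing of unequal-variance Gaussians is deliberately ignored — only
#' the between-means crossing enters the two-tail overlap computation).
#'
#' @param a,b [gaussian_estimate()] objects.
#' @return The crossing point in metres, with attribute `degenerate = TRUE`
#'   when the two means coincide (no unique between-means crossing; the common
#'   mean is returned).
#' @export
gaussian_crossing <- function(a, b) {
  stopifnot(is_number(a$mean), is_number(b$mean),
            is_number(a$variance), a$variance > 0,
            is_number(b$variance), b$variance > 0)
  if (a$mean > b$mean) { tmp <- a; a <- b; b <- tmp }
  if (a$mean == b$mean)
    return(structure(a$mean, degenerate = TRUE))
  if (a$variance == b$variance)
    return(structure((a$mean + b$mean) / 2, degenerate = FALSE))
  # equal log-density: quadratic in c
  A <- 1 / b$variance - 1 / a$variance
  B <- 2 * (a$mean / a$variance - b$mean / b$variance)
  C <- b$mean^2 / b$variance - a$mean^2 / a$variance +
    log(b$variance / a$variance)
  disc <- B^2 - 4 * A * C
  roots <- (-B + c(-1, 1) * sqrt(max(disc, 0))) / (2 * A)
  inside <- roots[roots >= a$mean & roots <= b$mean]
  if (length(inside) == 0L) # numerically on a boundary
    inside <- roots[which.min(pmin(abs(roots - a$mean), abs(roots - b$mean)))]
  structure(inside[1L], degenerate = FALSE)
}

#' Intersection-over-union overlap of two Gaussian estimates
#'
#' Computes the degree of overlap between the actual (delayed) and ideal
#' (zero-delay) bimodal estimate distributions. The overlap is the area lying
#' under both density curves: with `c` the between-means crossing point and the
#' actual distribution to the left of the ideal, it equals
#' `P[X_actual > c] + P[X_ideal < c]`. Normalising by the union (the total area
#' under the upper envelope, `2 - overlap`) yields the probability that the
#' delayed bimodal estimate falls where the ideal one would — the model's
#' index of bimodal-estimate accuracy during movement.
#'
#' For equal variances the closed form is `overlap = 2 * pnorm(-|dmu| / (2 *
#' sigma))`.
#'
#' @param actual,ideal [gaussian_estimate()] objects.
#' @return An object of class `"overlap_result"`: a list with elements
#'   `crossing_point` (m), `overlap_area`, `union_area`, `probability`, and
#'   `degenerate` (TRUE when the means coincide).
#' @examples
#' x <- gaussian_estimate(0, 1e-4)
#' overlap_probability(x, x)$probability # 1
#' @export
overlap_probability <- function(actual, ideal) {
  stopifnot(is_number(actual$variance), actual$variance > 0,
            is_number(ideal$variance), ideal$variance > 0)
  cc <- gaussian_crossing(actual, ideal)
  degenerate <- isTRUE(attr(cc, "degenerate"))
  cc <- as.numeric(cc)
  if (degenerate) {
    overlap <- 1
  } else {
    if (actual$mean <= ideal$mean) { left <- actual; right <- ideal }
    else { left <- ideal; right <- actual }
    overlap <- stats::pnorm(cc, left$mean, sqrt(left$variance),
                            lower.tail = FALSE) +
      stats::pnorm(cc, right$mean, sqrt(right$variance))
  }
  union <- 2 - overlap
  structure(list(crossing_point = cc,
                 overlap_area = overlap,
                 union_area = union,
                 probability = overlap / union,
                 degenerate = degenerate),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> crossing %.6g m; overlap %.6g / union %.6g; probability %.6g%s\n",
              x$crossing_point, x$overlap_area, x$union_area, x$probability,
              if (x$degenerate) " (degenerate: identical means)" else ""))
  invisible(x)
}

#' Sweep the overlap probability over speeds, delays, and variances
#'
#' For every combination of the supplied grids, computes the delay-induced
#' offset of the bimodal estimate and the intersection-over-union probability
#' that the delayed estimate matches the ideal one. The actual and ideal
#' distributions share the ideal bimodal variance (delay shifts the mean but
#' degrades no variance term), so the probability depends only on the ratio of
#' offset to bimodal standard deviation. Defaults reflect physiological
#' feedback latencies (vision ~70 ms, proprioception ~20 ms) and speeds up to
#' 0.5 m/s.
#'
#' @param speed Speeds in m/s (strictly increasing, non-empty).
#' @param tau_v,tau_p Visual / proprioceptive delays in s.
#' @param var_v,var_p Visual / proprioceptive variances in m^2.
#' @return A data.frame with columns `speed_mps`, `tau_v_s`, `tau_p_s`,
#'   `var_v_m2`, `var_p_m2`, `offset_m`, `probability`, one row per grid cell.
#' @examples
#' sw <- run_sweep(speed = c(0, 0.1, 0.187), tau_v = 0.07, tau_p = 0.02,
#'                 var_v = 1e-4, var_p = 1e-4)
#' @export
run_sweep <- function(speed = seq(0, 0.5, length.out = 51),
                      tau_v = 0.070, tau_p = 0.020,
                      var_v = 1e-4, var_p = 1e-4) {
  check_grid <- function(x, name, positive = FALSE, nonneg = FALSE) {
    if (length(x) == 0L || anyNA(x) || !is.numeric(x))
      stop_delaymle(sprintf("grid '%s' must be non-empty and numeric", name),
                    "delaymle_invalid_grid")
    if (length(x) > 1L && any(diff(x) <= 0))
      stop_delaymle(sprintf("grid '%s' must be strictly increasing", name),
                    "delaymle_invalid_grid")
    if (positive && any(x <= 0))
      stop_delaymle(sprintf("grid '%s' must be positive", name),
                    "delaymle_invalid_grid")
    if (nonneg && any(x < 0))
      stop_delaymle(sprintf("grid '%s' must be non-negative", name),
                    "delaymle_invalid_grid")
    x
  }
  check_grid(speed, "speed")
  check_grid(tau_v, "tau_v", nonneg = TRUE)
  check_grid(tau_p, "tau_p", nonneg = TRUE)
  check_grid(var_v, "var_v", positive = TRUE)
  check_grid(var_p, "var_p", positive = TRUE)
  g <- expand.grid(speed_mps = speed, tau_v_s = tau_v, tau_p_s = tau_p,
                   var_v_m2 = var_v, var_p_m2 = var_p,
                   KEEP.OUT.ATTRS = FALSE)
  s <- g$var_v_m2 + g$var_p_m2
  g$offset_m <- g$speed_mps *
    (g$var_p_m2 * g$tau_v_s + g$var_v_m2 * g$tau_p_s) / s
  sigma_b <- sqrt(g$var_v_m2 * g$var_p_m2 / s)
  # equal-variance closed form: both distributions carry the ideal bimodal sd
  overlap <- 2 * stats::pnorm(-abs(g$offset_m) / (2 * sigma_b))
  g$probability <- overlap / (2 - overlap)
  g
}
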