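#' Evaluate a Bezier curve
#'
#' Bernstein-polynomial evaluation of a planar Bezier curve at parameter
#' values `u`. Three control points give the quadratic arcs used as movement
#' stimuli; four give the cubic paths used for random passive transport.
#'
#' @param control_points Numeric matrix with one row per control point and two
#'   columns (x, y), in metres; at least 3 rows, with distinct first and last
#'   rows.
#' @param u Parameter values in `[0, 1]` (vectorised).
#' @return A matrix with `length(u)` rows and columns `x`, `y`.
#' @examples
#' arc <- rbind(c(0, 0), c(0.06, 0.075), c(0, 0.15))
#' bezier_point(arc, 0.5) # the 3 cm displaced arc midpoint: (0.03, 0.075)
#' @export
bezier_point <- function(control_points, u) {
  control_points <- validate_bezier(control_points)
  if (any(u < 0 | u > 1) || anyNA(u))
    stop_delaymle("'u' must lie in [0, 1]", "delaymle_invalid_parameter")
  n <- nrow(control_points) - 1L
  out <- matrix(0, length(u), 2L, dimnames = list(NULL, c("x", "y")))
  for (i in 0:n) {
    b <- choose(n, i) * u^i * (1 - u)^(n - i)
    out <- out + outer(b, control_points[i + 1L, ])
  }
  # u^0 at u=0 and (1-u)^0 at u=1 are handled by R as 1 (0^0 == 1), so the
  # endpoints evaluate exactly to the first/last control point.
  out
}

validate_bezier <- function(control_points) {
  control_points <- as.matrix(control_points)
  if (!is.numeric(control_points) || ncol(control_points) != 2L ||
      nrow(control_points) < 3L || anyNA(control_points))
    stop_delaymle("control points must be a numeric matrix with >= 3 rows and 2 columns",
                  "delaymle_invalid_parameter")
  if (all(control_points[1L, ] == control_points[nrow(control_points), ]))
    stop_delaymle("start and end control points must be distinct",
                  "delaymle_invalid_parameter")
  unname(control_points)
}

# hodograph: derivative of a degree-n Bezier is degree n-1 with control
# points n * diff(P)
bezier_speed_fun <- function(control_points) {
  n <- nrow(control_points) - 1L
  d <- n * diff(control_points)
  m <- nrow(d) - 1L
  function(u) {
    dx <- numeric(length(u)); dy <- numeric(length(u))
    for (i in 0:m) {
      b <- choose(m, i) * u^i * (1 - u)^(m - i)
      dx <- dx + b * d[i + 1L, 1L]
      dy <- dy + b * d[i + 1L, 2L]
    }
    sqrt(dx^2 + dy^2)
  }
}

#' Arc length of a Bezier path
#'
#' Numerical arc length (adaptive quadrature of the hodograph magnitude),
#' accurate to better than 1e-8 relative.
#'
#' @inheritParams bezier_point
#' @return Arc length in metres.
#' @examples
#' arc_length(rbind(c(0, 0), c(0.06, 0.075), c(0, 0.15))) # ~0.16473 m
#' @export
arc_length <- function(control_points) {
  control_points <- validate_bezier(control_points)
  f <- bezier_speed_fun(control_points)
  stats::integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}

#' Minimum-jerk progress profile
#'
#' Normalised distance travelled at time `t` of a movement of duration `T`
#' under the standard minimum-jerk (bell-shaped velocity) profile:
#' `s(r) = 10 r^3 - 15 r^4 + 6 r^5`, `r = t / T`. The rate `ds/dt` peaks at
#' the movement midpoint with value `1.875 / T`, so a path of length `L`
#' traversed in `T` seconds reaches peak speed `1.875 * L / T`.
#'
#' @param t Time(s) in seconds (vectorised); values outside `[0, T]` are
#'   clamped with a warning.
#' @param duration Movement duration `T` in seconds (> 0).
#' @return Progress fraction(s) in `[0, 1]`.
#' @export
minimum_jerk_progress <- function(t, duration) {
  if (!is_number(duration) || duration <= 0)
    stop_delaymle("'duration' must be a single positive number (s)",
                  "delaymle_invalid_parameter")
  if (any(t < 0 | t > duration)) {
    warning("times outside [0, duration] clamped")
    t <- pmin(pmax(t, 0), duration)
  }
  r <- t / duration
  10 * r^3 - 15 * r^4 + 6 * r^5
}

#' Sample a trajectory along a Bezier path
#'
#' Produces a uniformly sampled planar hand trajectory that follows the path
#' with arc-length fraction equal to the minimum-jerk progress profile, i.e. a
#' bell-shaped speed profile along the curve peaking at `1.875 * L / duration`
#' at the movement midpoint. Sampling defaults to 1 kHz, the task apparatus
#' recording rate.
#'
#' @inheritParams bezier_point
#' @param duration Movement duration in seconds (> 0).
#' @param rate Sampling rate in Hz (> 0; default 1000).
#' @return A data.frame of class `"trajectory"` with columns `t_s`, `x_m`,
#'   `y_m` and attribute `sample_rate`.
#' @examples
#' arc <- rbind(c(0, 0), c(0.06, 0.075), c(0, 0.15))
#' traj <- sample_trajectory(arc, duration = 1.6)
#' max(trajectory_speed(traj)) # ~1.875 * 0.16473 / 1.6 = 0.193 m/s
#' @export
sample_trajectory <- function(control_points, duration, rate = 1000) {
  control_points <- validate_bezier(control_points)
  if (!is_number(duration) || duration <= 0)
    stop_delaymle("'duration' must be a single positive number (s)",
                  "delaymle_invalid_parameter")
  if (!is_number(rate) || rate <= 0)
    stop_delaymle("'rate' must be a single positive number (Hz)",
                  "delaymle_invalid_parameter")
  # arc-length reparameterisation on a fine u-grid
  ngrid <- 8192L
  ug <- seq(0, 1, length.out = ngrid + 1L)
  sp <- bezier_speed_fun(control_points)(ug)
  h <- 1 / ngrid
  cum <- c(0, cumsum((sp[-1L] + sp[-length(sp)]) / 2 * h))
  cum <- cum / cum[length(cum)]
  t_s <- seq(0, duration, by = 1 / rate)
  frac <- minimum_jerk_progress(t_s, duration)
  u_t <- stats::approx(cum, ug, xout = frac, ties = "ordered")$y
  pos <- bezier_point(control_points, u_t)
  pos[1L, ] <- control_points[1L, ]
  pos[nrow(pos), ] <- control_points[nrow(control_points), ]
  out <- data.frame(t_s = t_s, x_m = pos[, 1L], y_m = pos[, 2L])
  attr(out, "sample_rate") <- rate
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Hand speed of a sampled trajectory
#'
#' Speed by centred finite differences of position (one-sided at the ends),
#' matching how velocity thresholds are applied to recorded kinematics.
#'
#' @param traj A trajectory data.frame (`t_s`, `x_m`, `y_m`).
#' @return Speed in m/s, one value per sample.
#' @export
trajectory_speed <- function(traj) {
  n <- nrow(traj)
  if (n < 3L)
    stop_delaymle("trajectory too short for finite differences",
                  "delaymle_invalid_parameter")
  t <- traj$t_s; x <- traj$x_m; y <- traj$y_m
  vx <- numeric(n); vy <- numeric(n)
  idx <- 2:(n - 1L)
  vx[idx] <- (x[idx + 1L] - x[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  vy[idx] <- (y[idx + 1L] - y[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  vx[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  vy[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  vx[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  vy[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  sqrt(vx^2 + vy^2)
}

#' Random passive-transport Bezier path
#'
#' Cubic Bezier from `start` to `end` whose two interior control points are
#' drawn uniformly from the start/end bounding box inflated laterally (in x)
#' by `lateral_margin`. Such paths prevent a passively moved participant from
#' using the transport itself to infer the endpoint. Deterministic under a
#' fixed RNG seed (see [set.seed()] or the `seed` argument).
#'
#' @param start,end Planar points (length-2 numeric, metres); must differ.
#' @param lateral_margin Lateral inflation of the sampling box in metres
#'   (default 0.06).
#' @param seed Optional integer seed; when given, the caller's RNG stream is
#'   left untouched.
#' @return A 4 x 2 control-point matrix.
#' @export
random_passive_path <- function(start, end, lateral_margin = 0.06,
                                seed = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 2L || length(end) != 2L || all(start == end))
    stop_delaymle("'start' and 'end' must be distinct planar points",
                  "delaymle_invalid_parameter")
  xr <- range(start[1L], end[1L]) + c(-1, 1) * lateral_margin
  yr <- range(start[2L], end[2L])
  with_seed(seed, {
    inner <- cbind(stats::runif(2L, xr[1L], xr[2L]),
                   stats::runif(2L, yr[1L], yr[2L]))
    rbind(start, inner, end, deparse.level = 0)
  })
}

#' Extract the movement endpoint by a velocity-threshold stop rule
#'
#' Finds the first window of `hold_duration` seconds throughout which hand
#' speed stays below `speed_threshold`, and returns the position at the final
#' sample of that window — the first time the hand has demonstrably come to a
#' stop, before any subsequent corrective motion. The static task uses
#' 0.06 m/s held for 500 ms; the dynamic task uses 0.05 m/s held for 2000 ms.
#'
#' @param traj A trajectory data.frame (`t_s`, `x_m`, `y_m`).
#' @param speed_threshold Speed threshold in m/s (> 0; default 0.06).
#' @param hold_duration Required below-threshold duration in s (> 0;
#'   default 0.5).
#' @return Named numeric `c(x, y)` in metres.
#' @export
extract_endpoint <- function(traj, speed_threshold = 0.06,
                             hold_duration = 0.5) {
  if (!is_number(speed_threshold) || speed_threshold <= 0 ||
      !is_number(hold_duration) || hold_duration <= 0)
    stop_delaymle("stop-rule parameters must be positive",
                  "delaymle_invalid_parameter")
  rate <- attr(traj, "sample_rate")
  if (is.null(rate)) rate <- 1 / stats::median(diff(traj$t_s))
  n_hold <- max(2L, round(hold_duration * rate))
  below <- trajectory_speed(traj) < speed_threshold
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= n_hold)
  if (length(ok) == 0L)
    stop_delaymle("no qualifying stop window: hand never held below threshold",
                  "delaymle_no_stop")
  idx <- starts[ok[1L]] + n_hold - 1L
  c(x = traj$x_m[idx], y = traj$y_m[idx])
}

#' Extract the movement midpoint at the halfway line
#'
#' Returns the x-position at the first upward crossing of `y = halfway`
#' (linearly interpolated between the bracketing samples). The dynamic task
#' scores the horizontal position when the hand has moved 7.5 cm along the
#' y-axis, half the 15 cm movement extent; later re-crossings (corrections)
#' are ignored.
#'
#' @param traj A trajectory data.frame (`t_s`, `x_m`, `y_m`).
#' @param halfway The y-coordinate of the halfway line in metres
#'   (default 0.075).
#' @return The interpolated x-position in metres (scalar).
#' @export
extract_midpoint <- function(traj, halfway = 0.075) {
  y <- traj$y_m
  n <- length(y)
  cross <- which(y[-n] < halfway & y[-1L] >= halfway)
  if (length(cross) == 0L) {
    if (y[1L] >= halfway && any(y >= halfway))
      stop_delaymle("trajectory starts beyond the halfway line",
                    "delaymle_no_crossing")
    stop_delaymle("trajectory never crosses the halfway line",
                  "delaymle_no_crossing")
  }
  i <- cross[1L]
  f <- (halfway - y[i]) / (y[i + 1L] - y[i])
  traj$x_m[i] + f * (traj$x_m[i + 1L] - traj$x_m[i])
}

#' Quadratic arc stimulus path
#'
#' The symmetric three-control-point arc used as a movement stimulus: it
#' starts at the origin, ends `extent` metres straight ahead, and passes at
#' its midpoint `midpoint_x` metres to the side of the midline (the middle
#' control point sits at `2 * midpoint_x` so that the Bernstein midpoint lands
#' exactly at `midpoint_x`).
#'
#' @param midpoint_x Signed lateral midpoint displacement in metres
#'   (e.g. 0.03 for a rightward arc).
#' @param extent Forward movement extent in metres (default 0.15).
#' @return A 3 x 2 control-point matrix.
#' @examples
#' bezier_point(arc_path(0.03), 0.5) # (0.03, 0.075)
#' @export
arc_path <- function(midpoint_x, extent = 0.15) {
  rbind(c(0, 0), c(2 * midpoint_x, extent / 2), c(0, extent))
}
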