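#' Gaze / stimulus trajectory of one trial
#'
#' Stimulus-center positions over time in the master-image (mosaic) frame.
#' Coordinates follow the package convention: x rightward, y downward,
#' arcmin. Angles reported by the drift metrics are measured positive
#' counterclockwise on the screen, so a displacement of (0, -1) (screen up)
#' has direction +90 deg.
#'
#' @param t_ms Sample times in ms, strictly increasing.
#' @param x,y Positions in arcmin.
#' @param trial Trial identifier.
#' @param window Stimulus-on window `c(onset, offset)` in ms (default
#'   `c(0, 500)`).
#' @param frame_rate_hz Nominal sampling rate (default 30).
#' @return Object of class `gaze_trace`.
#' @export
gaze_trace <- function(t_ms, x, y, trial = 1L, window = c(0, 500),
                       frame_rate_hz = 30) {
  stopifnot(is.numeric(t_ms), length(t_ms) == length(x),
            length(x) == length(y))
  if (any(diff(t_ms) <= 0)) stop("trace timestamps must be strictly increasing")
  if (window[2] <= window[1]) stop("window offset must follow onset")
  if (window[1] < t_ms[1] || window[2] > t_ms[length(t_ms)])
    stop("stimulus-on window must lie within the trace time span")
  structure(list(t_ms = as.numeric(t_ms), x = as.numeric(x),
                 y = as.numeric(y), trial = trial,
                 window = as.numeric(window), frame_rate_hz = frame_rate_hz),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> trial %s: %d samples over %.0f ms, window [%g, %g] ms\n",
              format(x$trial), length(x$t_ms), diff(range(x$t_ms)),
              x$window[1], x$window[2]))
  invisible(x)
}

.window_idx <- function(trace) {
  which(trace$t_ms >= trace$window[1] & trace$t_ms <= trace$window[2])
}

## wrap degrees into (-180, 180]
.wrap180 <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

## screen-frame direction (deg, CCW positive, up = +90) of displacement
.direction_deg <- function(dx, dy) atan2(-dy, dx) * 180 / pi

#' Detect microsaccades in a gaze trace
#'
#' Median-based velocity-threshold detector in the Engbert-Kliegl style:
#' velocities from a 5-sample moving window, per-axis thresholds at `lambda`
#' median-based standard deviations, events as runs of supra-threshold
#' samples lasting at least `min_dur_ms`. Deterministic for fixed input.
#'
#' Because slow drift can have nearly constant velocity (zero median-based
#' variance), the per-axis threshold is floored at `velocity_floor`:
#' microsaccades exceed a couple of deg/s peak velocity, well above any
#' drift.
#'
#' @param trace A [gaze_trace()].
#' @param lambda Threshold multiplier (default 6).
#' @param min_dur_ms Minimum event duration in ms (default 6).
#' @param velocity_floor Minimum per-axis velocity threshold in arcmin/s
#'   (default 120, i.e. 2 deg/s).
#' @return data.frame with columns `start_ms`, `end_ms`, `peak_velocity`
#'   (arcmin/s), `amplitude` (arcmin); zero rows when no event is found.
#' @export
detect_microsaccades <- function(trace, lambda = 6, min_dur_ms = 6,
                                 velocity_floor = 120) {
  stopifnot(inherits(trace, "gaze_trace"))
  n <- length(trace$t_ms)
  if (diff(range(trace$t_ms)) < 100)
    stop("need at least 100 ms of samples for microsaccade detection")
  dt <- stats::median(diff(trace$t_ms)) / 1000  # s
  vx <- vy <- rep(NA_real_, n)
  if (n >= 5) {
    i <- 3:(n - 2)
    vx[i] <- (trace$x[i + 2] + trace$x[i + 1] - trace$x[i - 1] - trace$x[i - 2]) /
      (6 * dt)
    vy[i] <- (trace$y[i + 2] + trace$y[i + 1] - trace$y[i - 1] - trace$y[i - 2]) /
      (6 * dt)
  }
  ## edge samples: 3-point central difference so events at the trace ends
  ## are still seen
  if (n >= 3) {
    for (j in c(2, n - 1)) {
      if (is.na(vx[j])) {
        vx[j] <- (trace$x[j + 1] - trace$x[j - 1]) / (2 * dt)
        vy[j] <- (trace$y[j + 1] - trace$y[j - 1]) / (2 * dt)
      }
    }
  }
  msd <- function(v) {
    v <- v[!is.na(v)]
    s <- sqrt(stats::median(v^2) - stats::median(v)^2)
    if (!is.finite(s) || s < 1e-9) s <- 1e-9
    s
  }
  ex <- max(lambda * msd(vx), velocity_floor)
  ey <- max(lambda * msd(vy), velocity_floor)
  hot <- (vx / ex)^2 + (vy / ey)^2 > 1
  hot[is.na(hot)] <- FALSE
  ev <- list()
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    if (trace$t_ms[i1] - trace$t_ms[i0] + dt * 1000 < min_dur_ms) next
    spd <- sqrt(vx[i0:i1]^2 + vy[i0:i1]^2)
    ev[[length(ev) + 1]] <- data.frame(
      start_ms = trace$t_ms[i0], end_ms = trace$t_ms[i1],
      peak_velocity = max(spd, na.rm = TRUE),
      amplitude = sqrt((trace$x[i1] - trace$x[i0])^2 +
                       (trace$y[i1] - trace$y[i0])^2))
  }
  if (!length(ev))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      peak_velocity = numeric(0), amplitude = numeric(0)))
  do.call(rbind, ev)
}

#' Trial exclusion rule
#'
#' A trial is excluded when a microsaccade overlaps the stimulus-on window or
#' when the trace has a sampling gap (blink surrogate) longer than
#' `max_gap_ms` inside the window.
#'
#' @param trace A [gaze_trace()].
#' @param events Optional precomputed [detect_microsaccades()] result.
#' @param max_gap_ms Longest tolerated sample gap in ms (default 50).
#' @return Logical scalar with attribute `reason` (`"ok"`, `"microsaccade"`
#'   or `"gap"`).
#' @export
trial_excluded <- function(trace, events = NULL, max_gap_ms = 50) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (is.null(events)) events <- detect_microsaccades(trace)
  w <- trace$window
  if (nrow(events) &&
      any(events$start_ms <= w[2] & events$end_ms >= w[1]))
    return(structure(TRUE, reason = "microsaccade"))
  idx <- .window_idx(trace)
  if (length(idx) >= 2 && max(diff(trace$t_ms[idx])) > max_gap_ms)
    return(structure(TRUE, reason = "gap"))
  structure(FALSE, reason = "ok")
}

#' Drift length and velocity
#'
#' Drift length is the concatenated vector sum of all frame-wise motion
#' vectors inside the stimulus-on window: the sum of the Euclidean norms of
#' successive displacements (a closed loop therefore has its full path
#' length, not zero). Velocity is length divided by the window duration.
#'
#' @param trace A [gaze_trace()].
#' @return List with `length` (arcmin), `velocity` (arcmin/s), `n_frames`.
#' @export
drift_length <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  idx <- .window_idx(trace)
  if (length(idx) < 2) stop("fewer than 2 trace samples inside the window")
  steps <- sqrt(diff(trace$x[idx])^2 + diff(trace$y[idx])^2)
  len <- sum(steps)
  list(length = len,
       velocity = len / (diff(trace$window) / 1000),
       n_frames = length(idx))
}

#' Drift direction in retinal coordinates
#'
#' Direction of the net onset-to-offset displacement, degrees CCW with
#' screen-up = +90.
#'
#' @param trace A [gaze_trace()].
#' @return Angle in `(-180, 180]`, or `NA` (flagged undefined) for zero net
#'   displacement.
#' @export
drift_direction <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  idx <- .window_idx(trace)
  dx <- trace$x[idx[length(idx)]] - trace$x[idx[1]]
  dy <- trace$y[idx[length(idx)]] - trace$y[idx[1]]
  if (dx == 0 && dy == 0) return(NA_real_)
  .wrap180(.direction_deg(dx, dy))
}

#' Drift angle relative to a landmark
#'
#' Signed angle between the onset-to-offset drift vector and the line from
#' the onset location to the landmark; 0 means drifting straight at the
#' landmark, 180 straight away, positive counterclockwise.
#'
#' @param trace A [gaze_trace()].
#' @param landmark Numeric `c(x, y)` in arcmin.
#' @return Angle in `(-180, 180]`; `NA` when the net displacement is zero or
#'   the onset coincides with the landmark.
#' @export
angle_to_landmark <- function(trace, landmark) {
  stopifnot(inherits(trace, "gaze_trace"))
  idx <- .window_idx(trace)
  ox <- trace$x[idx[1]]; oy <- trace$y[idx[1]]
  dx <- trace$x[idx[length(idx)]] - ox
  dy <- trace$y[idx[length(idx)]] - oy
  lx <- landmark[[1]] - ox; ly <- landmark[[2]] - oy
  if ((dx == 0 && dy == 0) || (lx == 0 && ly == 0)) return(NA_real_)
  .wrap180(.direction_deg(dx, dy) - .direction_deg(lx, ly))
}

## quadrant of a landmark-relative angle: 0 toward, 1 ccw, 2 away, 3 cw
## (half-open bins [-45, 45), [45, 135), [135, 225), [225, 315))
.quadrant <- function(theta) {
  t <- .wrap180(theta)
  t[t == 180] <- -180
  floor((t + 45) / 90) %% 4
}

#' Directionality tuning ratio
#'
#' Ratio of the relative frequency of drifts within +-45 deg of the landmark
#' direction to the mean relative frequency of the other three quadrants
#' (half-open bins). 1 means no directional preference.
#'
#' @param angles Landmark-relative angles in degrees; `NA`s are dropped.
#' @return Ratio (possibly `Inf` with a warning when the three far quadrants
#'   are all empty).
#' @export
tuning_ratio <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("no defined angles")
  q <- .quadrant(angles)
  f <- tabulate(q + 1, nbins = 4) / length(q)
  far <- mean(f[2:4])
  if (far == 0) {
    warning("all drifts within +-45 deg of the landmark; tuning ratio is infinite")
    return(Inf)
  }
  f[1] / far
}

#' Quadrant frequency table of landmark-relative angles
#'
#' @param angles Angles in degrees (`NA` dropped).
#' @return Named numeric: `toward`, `ccw`, `away`, `cw` (sums to 1).
#' @export
quadrant_frequencies <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("no defined angles")
  f <- tabulate(.quadrant(angles) + 1, nbins = 4) / length(angles)
  stats::setNames(f, c("toward", "ccw", "away", "cw"))
}

#' Rayleigh test for circular non-uniformity
#'
#' Mean resultant length and the standard Rayleigh approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` with `Rn = n * Rbar`.
#'
#' @param angles Angles in degrees (`NA` dropped); at least 5 required.
#' @return List with `r_bar`, `p`, `n`.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 5) stop("Rayleigh test requires at least 5 angles")
  a <- angles * pi / 180
  r_bar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  rn <- n * r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - rn^2)) - (1 + 2 * n))
  list(r_bar = r_bar, p = min(p, 1), n = n)
}

#' One-SD isoline area (ISOA)
#'
#' Area of the region enclosed by the kernel-density contour containing
#' `mass` (default 68.27%) of the probability mass of a bivariate Gaussian
#' kernel estimate of the point cloud. Computed on a regular grid; disjoint
#' contour lobes are summed.
#'
#' @param x,y Point coordinates (arcmin); or `x` a two-column matrix.
#' @param mass Enclosed probability mass (default 0.6827).
#' @param bandwidth Kernel SD per axis; default Silverman-style
#'   [stats::bw.nrd0()] (Silverman rule of thumb) per axis.
#' @param grid_step Grid resolution in arcmin (default 0.1).
#' @return Object of class `isoa_result`: list with `area` (arcmin^2),
#'   `level`, `bandwidth`, `mass`, `contours` (list of polygons from
#'   [grDevices::contourLines()]).
#' @export
isoa <- function(x, y = NULL, mass = 0.6827, bandwidth = NULL,
                 grid_step = 0.1) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("ISOA requires at least 10 points")
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12)
    stop("all points identical; ISOA undefined")
  if (is.null(bandwidth)) {
    bw1 <- function(v) {
      h <- tryCatch(stats::bw.nrd0(v), error = function(e) 0)
      if (!is.finite(h) || h <= 0) h <- max(stats::sd(v), 1e-6)
      h
    }
    bandwidth <- c(bw1(x), bw1(y))
  }
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  gx <- seq(min(x) - 4 * bandwidth[1], max(x) + 4 * bandwidth[1], by = grid_step)
  gy <- seq(min(y) - 4 * bandwidth[2], max(y) + 4 * bandwidth[2], by = grid_step)
  kx <- outer(gx, x, function(g, p) stats::dnorm(g - p, sd = bandwidth[1]))
  ky <- outer(gy, y, function(g, p) stats::dnorm(g - p, sd = bandwidth[2]))
  f <- (kx %*% t(ky)) / n                      # [gx, gy]
  cell <- grid_step^2
  ord <- order(f, decreasing = TRUE)
  cum <- cumsum(f[ord]) * cell
  ## level such that cells above it hold `mass` of the (discretized) total
  total <- sum(f) * cell
  k <- which(cum >= mass * total)[1]
  level <- f[ord[k]]
  area <- k * cell
  contours <- grDevices::contourLines(gx, gy, f, levels = level)
  structure(list(area = area, level = level, bandwidth = bandwidth,
                 mass = mass, contours = contours),
            class = "isoa_result")
}

#' @export
print.isoa_result <- function(x, ...) {
  cat(sprintf("<isoa_result> area %.1f arcmin^2 (%.1f%% mass, bw %.2f/%.2f arcmin)\n",
              x$area, 100 * x$mass, x$bandwidth[1], x$bandwidth[2]))
  invisible(x)
}

#' Distance convergence toward a landmark
#'
#' `1 - offset_distance / onset_distance`: positive when the drift brought
#' the stimulus closer to the landmark.
#'
#' @param trace A [gaze_trace()].
#' @param landmark Numeric `c(x, y)` arcmin.
#' @return Fraction (can be negative); `NA` when the onset coincides with
#'   the landmark.
#' @export
convergence_ratio <- function(trace, landmark) {
  stopifnot(inherits(trace, "gaze_trace"))
  idx <- .window_idx(trace)
  d <- function(i) sqrt((trace$x[i] - landmark[[1]])^2 +
                        (trace$y[i] - landmark[[2]])^2)
  on <- d(idx[1]); off <- d(idx[length(idx)])
  if (on == 0) return(NA_real_)
  1 - off / on
}

#' Achieved and potential sampling gain
#'
#' Achieved gain is the maximum sampling cone density during the trial
#' divided by the density at stimulus onset. Potential gain is the density
#' the eye could have reached by re-centering on the CDC: the density-map
#' value at the CDC divided by the onset density.
#'
#' @param series A [trial_sampling_series()] result.
#' @param cdc_density Density-map value at the CDC (cones/deg^2), for the
#'   potential gain.
#' @return `sampling_gain()`: achieved gain (ratio). `potential_sampling_gain()`:
#'   potential gain (ratio).
#' @export
sampling_gain <- function(series) {
  stopifnot(inherits(series, "sampling_series"))
  on <- series$onset_density
  if (!is.finite(on)) stop("onset frame has undefined sampling density")
  max(series$frames$density, na.rm = TRUE) / on
}

#' @rdname sampling_gain
#' @export
potential_sampling_gain <- function(series, cdc_density) {
  stopifnot(inherits(series, "sampling_series"), cdc_density > 0)
  on <- series$onset_density
  if (!is.finite(on)) stop("onset frame has undefined sampling density")
  cdc_density / on
}

#' Per-trial drift metric bundle
#'
#' Applies the exclusion rule and computes all scalar drift metrics of one
#' trial against the landmark set.
#'
#' @param trace A [gaze_trace()].
#' @param landmarks A [foveolar_landmarks()] (PRL optional).
#' @return One-row data.frame: `trial`, `excluded`, `reason`, `drift_length`,
#'   `drift_velocity`, `theta_retina`, `theta_cdc`, `theta_prl`, `theta_pcd`,
#'   `onset_distance_cdc`, `convergence_cdc`, `convergence_prl`,
#'   `convergence_pcd`.
#' @export
drift_metrics <- function(trace, landmarks) {
  stopifnot(inherits(trace, "gaze_trace"), inherits(landmarks, "foveolar_landmarks"))
  excl <- trial_excluded(trace)
  idx <- .window_idx(trace)
  cdc <- landmarks$cdc; pcd <- landmarks$pcd$location; prl <- landmarks$prl
  dl <- drift_length(trace)
  onset_d_cdc <- sqrt((trace$x[idx[1]] - cdc[["x"]])^2 +
                      (trace$y[idx[1]] - cdc[["y"]])^2)
  data.frame(
    trial = trace$trial,
    excluded = as.logical(excl), reason = attr(excl, "reason"),
    drift_length = dl$length, drift_velocity = dl$velocity,
    theta_retina = drift_direction(trace),
    theta_cdc = angle_to_landmark(trace, cdc),
    theta_prl = if (is.null(prl)) NA_real_ else angle_to_landmark(trace, prl),
    theta_pcd = angle_to_landmark(trace, pcd),
    onset_distance_cdc = onset_d_cdc,
    convergence_cdc = convergence_ratio(trace, cdc),
    convergence_prl = if (is.null(prl)) NA_real_ else convergence_ratio(trace, prl),
    convergence_pcd = convergence_ratio(trace, pcd))
}

#' Aggregate directionality statistics per landmark
#'
#' Pools included trials and reports, for each landmark (CDC, PRL, PCD),
#' the quadrant frequency table, tuning ratio, and Rayleigh test.
#'
#' @param metrics data.frame of per-trial rows from [drift_metrics()].
#' @return List of per-landmark lists (`cdc`, `prl`, `pcd`), each with
#'   `frequencies`, `tuning_ratio`, `rayleigh`, `n`; plus `n_excluded` and
#'   `exclusion_reasons`.
#' @export
aggregate_directionality <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  inc <- metrics[!metrics$excluded, , drop = FALSE]
  if (!nrow(inc)) stop("no included trials")
  one <- function(th) {
    th <- th[!is.na(th)]
    if (!length(th)) return(NULL)
    list(frequencies = quadrant_frequencies(th),
         tuning_ratio = tuning_ratio(th),
         rayleigh = if (length(th) >= 5) rayleigh_test(th) else NULL,
         n = length(th))
  }
  list(cdc = one(inc$theta_cdc),
       prl = one(inc$theta_prl),
       pcd = one(inc$theta_pcd),
       n_excluded = sum(metrics$excluded),
       exclusion_reasons = table(metrics$reason[metrics$excluded]))
}
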