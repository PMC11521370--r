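#' Parameters for synthetic foveolar cone mosaics
#'
#' The generator emulates a quasi-hexagonal foveolar mosaic with a radial
#' density gradient: density declines exponentially with eccentricity from
#' the peak location, `rho(r) = rho0 * exp(-gradient * r)` (r in arcmin),
#' and cone positions get independent Gaussian jitter proportional to the
#' local lattice spacing.
#'
#' @param center_density Peak density `rho0` in cones/deg^2 (default 14000,
#'   inside the 8000-20000 envelope typical of human foveolae).
#' @param gradient Fractional density decline per arcmin of eccentricity
#'   (default 0.02).
#' @param jitter Positional jitter SD as a fraction of local spacing
#'   (default 0.12; must be < 0.3).
#' @param field_arcmin Field width and height in arcmin (default `c(24, 24)`).
#' @param peak Density-peak location `c(x, y)` arcmin (default field center).
#' @param pixel_scale Arcmin per pixel for the resulting mosaic (default 0.1).
#' @return Object of class `mosaic_params`.
#' @export
mosaic_params <- function(center_density = 14000, gradient = 0.02,
                          jitter = 0.12, field_arcmin = c(24, 24),
                          peak = NULL, pixel_scale = 0.1) {
  stopifnot(center_density >= 2000, center_density <= 30000,
            gradient >= 0, jitter >= 0, jitter < 0.3,
            all(field_arcmin > 0))
  if (is.null(peak)) peak <- field_arcmin / 2
  structure(list(center_density = center_density, gradient = gradient,
                 jitter = jitter, field_arcmin = field_arcmin,
                 peak = c(x = peak[[1]], y = peak[[2]]),
                 pixel_scale = pixel_scale),
            class = "mosaic_params")
}

#' Generate a synthetic cone mosaic with known ground truth
#'
#' Builds a hexagonal lattice at the peak density, warps it radially so the
#' cumulative cone count matches the exponential density profile, applies
#' Gaussian positional jitter scaled to the local spacing, and clips to the
#' field.
#'
#' @param params A [mosaic_params()].
#' @param seed RNG seed (default 1).
#' @return List with `mosaic` (a [cone_mosaic()]) and `truth` (peak location,
#'   `rho0`, `gradient`, and the density function `density_fun(r)`).
#' @export
generate_mosaic <- function(params = mosaic_params(), seed = 1) {
  stopifnot(inherits(params, "mosaic_params"))
  set.seed(seed)
  rho0_am <- params$center_density / 3600          # cones / arcmin^2
  s0 <- sqrt(2 / (sqrt(3) * rho0_am))              # hex spacing, arcmin
  W <- params$field_arcmin[1]; H <- params$field_arcmin[2]
  px <- params$peak["x"]; py <- params$peak["y"]
  rmax <- sqrt(max(px, W - px)^2 + max(py, H - py)^2) + 3 * s0
  ## warp radius: uniform-lattice radius r_u -> target radius r so that
  ## cumulative counts match the exponential profile
  g <- params$gradient
  if (g > 0) {
    rr <- seq(0, 3 * rmax, length.out = 2048)
    ru <- sqrt(2 * (1 - exp(-g * rr) * (1 + g * rr)) / g^2)
    warp <- stats::approxfun(ru, rr, rule = 2)
  } else {
    warp <- identity
  }
  ## hex lattice covering the pre-warp disk of radius rmax (warp only expands)
  dy <- s0 * sqrt(3) / 2
  rows <- seq(-ceiling(rmax / dy), ceiling(rmax / dy))
  pts <- do.call(rbind, lapply(rows, function(i) {
    xs <- seq(-ceiling(rmax / s0), ceiling(rmax / s0)) * s0 +
      (i %% 2) * s0 / 2
    cbind(xs, i * dy)
  }))
  r_u <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  keep <- r_u <= rmax
  pts <- pts[keep, , drop = FALSE]; r_u <- r_u[keep]
  scl <- ifelse(r_u > 0, warp(r_u) / r_u, 1)
  x <- px + pts[, 1] * scl
  y <- py + pts[, 2] * scl
  r <- sqrt((x - px)^2 + (y - py)^2)
  s_local <- s0 * exp(g * r / 2)
  x <- x + stats::rnorm(length(x), 0, params$jitter * s_local)
  y <- y + stats::rnorm(length(y), 0, params$jitter * s_local)
  inside <- x > 0 & x < W & y > 0 & y < H
  x <- x[inside]; y <- y[inside]
  if (length(x) < 300)
    stop("field too small: only ", length(x), " cones generated (need >= 300)")
  truth <- list(peak = params$peak, rho0 = params$center_density,
                gradient = g,
                density_fun = function(r) params$center_density * exp(-g * r))
  list(mosaic = cone_mosaic(x, y, extent = c(W, H),
                            pixel_scale = params$pixel_scale),
       truth = truth)
}

#' Parameters for synthetic fixational drift traces
#'
#' Step lengths are gamma-distributed with a per-trial lognormal scale
#' multiplier; step directions are von Mises around the trial's
#' start-to-target bearing with concentration `kappa` (`kappa = 0` is
#' isotropic). Defaults target the drift statistics of foveolar fixation:
#' ~6.5 arcmin median path length per 500 ms window at 30 Hz, trial-to-trial
#' spread spanning roughly 2.5-17 arcmin.
#'
#' @param frame_rate_hz Sampling rate (default 30).
#' @param duration_ms Trial duration (default 1000).
#' @param window Stimulus-on window in ms (default `c(300, 800)`).
#' @param step_shape Gamma shape of per-frame step length (default 2).
#' @param step_scale Gamma scale in arcmin (default tuned so the median
#'   windowed path length is ~6.5 arcmin).
#' @param scale_sdlog SD of the per-trial lognormal scale multiplier
#'   (default 0.45).
#' @param kappa Von Mises concentration of the directional bias (default 0).
#' @param ms_rate Microsaccade injection probability per trial (default 0).
#' @param ms_amplitude Injected microsaccade amplitude in arcmin
#'   (default 30).
#' @return Object of class `drift_params`.
#' @export
drift_params <- function(frame_rate_hz = 30, duration_ms = 1000,
                         window = c(300, 800), step_shape = 2,
                         step_scale = NULL, scale_sdlog = 0.45,
                         kappa = 0, ms_rate = 0, ms_amplitude = 30) {
  stopifnot(frame_rate_hz > 0, duration_ms > 0, kappa >= 0,
            step_shape > 0, scale_sdlog >= 0, ms_rate >= 0, ms_rate <= 1)
  if (is.null(step_scale)) {
    n_window_steps <- diff(window) / 1000 * frame_rate_hz
    step_scale <- 6.5 / (n_window_steps * step_shape)
  }
  stopifnot(step_scale > 0)
  structure(list(frame_rate_hz = frame_rate_hz, duration_ms = duration_ms,
                 window = window, step_shape = step_shape,
                 step_scale = step_scale, scale_sdlog = scale_sdlog,
                 kappa = kappa, ms_rate = ms_rate,
                 ms_amplitude = ms_amplitude),
            class = "drift_params")
}

#' Von Mises random angles
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Radians in `(-pi, pi]` around `mu`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi) + mu
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(0)
    while (length(th) < n) {
      m <- max(16, ceiling(1.2 * (n - length(th))))
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      th <- c(th, mu + sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)))
    }
    th <- th[seq_len(n)]
  }
  w <- (th + pi) %% (2 * pi)
  w - pi + 2 * pi * (w == 0)   # (-pi, pi]
}

#' Generate one synthetic drift trace
#'
#' Cumulative random walk from `start`: gamma step lengths, von Mises step
#' directions around the start-to-target bearing (isotropic when `kappa = 0`
#' or no target). Optionally injects one labelled ballistic microsaccade at
#' a random frame.
#'
#' @param params A [drift_params()].
#' @param start Start position `c(x, y)` arcmin.
#' @param target Optional bias target `c(x, y)` arcmin (e.g. the CDC).
#' @param trial Trial id.
#' @param seed Optional RNG seed.
#' @return List with `trace` (a [gaze_trace()]) and `labels` (data.frame of
#'   injected microsaccades: `t_ms`, `amplitude`; zero rows when none).
#' @export
generate_drift_trace <- function(params = drift_params(), start = c(0, 0),
                                 target = NULL, trial = 1L, seed = NULL) {
  stopifnot(inherits(params, "drift_params"))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1000 / params$frame_rate_hz
  t_ms <- seq(0, params$duration_ms, by = dt)
  n_steps <- length(t_ms) - 1
  scale_mult <- stats::rlnorm(1, 0, params$scale_sdlog)
  len <- stats::rgamma(n_steps, shape = params$step_shape,
                       scale = params$step_scale * scale_mult)
  if (!is.null(target) && params$kappa > 0) {
    ## closed-loop bias: re-aim at the target from the current position each
    ## step, so the walk homes in rather than overshooting
    dx <- dy <- numeric(n_steps)
    cx <- start[[1]]; cy <- start[[2]]
    for (i in seq_len(n_steps)) {
      bearing <- atan2(target[[2]] - cy, target[[1]] - cx)
      phi <- rvonmises(1, bearing, params$kappa)
      dx[i] <- len[i] * cos(phi); dy[i] <- len[i] * sin(phi)
      cx <- cx + dx[i]; cy <- cy + dy[i]
    }
  } else {
    phi <- stats::runif(n_steps, -pi, pi)
    dx <- len * cos(phi); dy <- len * sin(phi)
  }
  labels <- data.frame(t_ms = numeric(0), amplitude = numeric(0))
  if (params$ms_rate > 0 && stats::runif(1) < params$ms_rate) {
    i <- sample.int(n_steps, 1)
    dir <- stats::runif(1, -pi, pi)
    dx[i] <- dx[i] + params$ms_amplitude * cos(dir)
    dy[i] <- dy[i] + params$ms_amplitude * sin(dir)
    labels <- data.frame(t_ms = t_ms[i + 1], amplitude = params$ms_amplitude)
  }
  x <- start[[1]] + cumsum(c(0, dx))
  y <- start[[2]] + cumsum(c(0, dy))
  list(trace = gaze_trace(t_ms, x, y, trial = trial, window = params$window,
                          frame_rate_hz = params$frame_rate_hz),
       labels = labels)
}

#' Generate a full synthetic psychophysical session
#'
#' Mirrors the experimental protocol: a cone mosaic with landmarks, QUEST
#' staircases driving Snellen-E gap sizes, a per-trial drift trace starting
#' near the PRL and (optionally) biased toward the CDC, and 4AFC responses
#' from a synthetic observer. When `observer` is `NULL` the observer's true
#' threshold is tied to the eye's Nyquist limit as
#' `alpha = alpha_vs_nyquist * nyquist_arcsec`, so denser mosaics yield
#' lower thresholds.
#'
#' @param mosaic_pars A [mosaic_params()].
#' @param drift_pars A [drift_params()].
#' @param observer A [synthetic_observer()] or `NULL`.
#' @param n_runs QUEST runs (default 5).
#' @param n_trials Trials per run (default 20).
#' @param alpha_vs_nyquist Observer threshold as a fraction of the Nyquist
#'   limit when `observer` is `NULL` (default 0.84).
#' @param prl_offset PRL displacement from the CDC, arcmin
#'   (default `c(1.5, 1)`).
#' @param onset_sd SD of trial start positions around the PRL (default 2
#'   arcmin).
#' @param map_stride Density-map decimation used for landmarks (default 4).
#' @param seed RNG seed (default 1).
#' @return Object of class `synthetic_session`: list with `mosaic`,
#'   `patches`, `map`, `landmarks`, `trials` (pooled data.frame), `traces`
#'   (list of [gaze_trace()]), `ms_labels`, `observer`, `truth`.
#' @export
generate_session <- function(mosaic_pars = mosaic_params(),
                             drift_pars = drift_params(kappa = 2),
                             observer = NULL, n_runs = 5, n_trials = 20,
                             alpha_vs_nyquist = 0.84,
                             prl_offset = c(1.5, 1), onset_sd = 2,
                             map_stride = 4, seed = 1) {
  gm <- generate_mosaic(mosaic_pars, seed = seed)
  patches <- tessellate(gm$mosaic)
  map <- density_map(gm$mosaic, patches, stride = map_stride)
  prl_guess <- cone_density_centroid(map) + c(prl_offset[[1]], prl_offset[[2]])
  lm <- foveolar_landmarks(map, prl = prl_guess, mosaic = gm$mosaic,
                           patches = patches)
  if (is.null(observer))
    observer <- synthetic_observer(alpha_vs_nyquist * lm$nyquist_arcsec)
  set.seed(seed + 1)
  dirs <- c("up", "down", "left", "right")
  traces <- list(); labels <- list(); runs <- list()
  trial_id <- 0L
  for (r in seq_len(n_runs)) {
    state <- quest_create()
    rec <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      trial_id <- trial_id + 1L
      gap <- .quantize_gap(10^quest_next(state), mosaic_pars$pixel_scale)
      orient <- sample(dirs, 1)
      start <- c(lm$prl[["x"]] + stats::rnorm(1, 0, onset_sd),
                 lm$prl[["y"]] + stats::rnorm(1, 0, onset_sd))
      start <- pmin(pmax(start, 2), gm$mosaic$extent - 2)
      gt <- generate_drift_trace(drift_pars, start = start,
                                 target = c(lm$cdc[["x"]], lm$cdc[["y"]]),
                                 trial = trial_id)
      traces[[trial_id]] <- gt$trace
      if (nrow(gt$labels)) {
        gt$labels$trial <- trial_id
        labels[[length(labels) + 1]] <- gt$labels
      }
      correct <- stats::runif(1) < .observer_p(observer, gap)
      response <- if (correct) orient else sample(setdiff(dirs, orient), 1)
      state <- quest_update(state, log10(gap), correct)
      rec[[i]] <- data.frame(run = r, trial = i, gap_arcsec = gap,
                             orientation = orient, response = response,
                             correct = correct)
    }
    runs[[r]] <- do.call(rbind, rec)
  }
  structure(list(mosaic = gm$mosaic, patches = patches, map = map,
                 landmarks = lm, trials = pool_runs(runs), traces = traces,
                 ms_labels = if (length(labels)) do.call(rbind, labels)
                             else data.frame(t_ms = numeric(0),
                                             amplitude = numeric(0),
                                             trial = integer(0)),
                 observer = observer,
                 truth = c(gm$truth, list(observer_alpha = observer$alpha_arcsec,
                                          seed = seed))),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d trials, %d traces; observer alpha %.1f arcsec\n",
              nrow(x$trials), length(x$traces), x$observer$alpha_arcsec))
  invisible(x)
}
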