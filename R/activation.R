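#' Cone light-capture apertures
#'
#' Each cone's light acceptance aperture is a circularly symmetric Gaussian
#' profile. Its diameter is 48% of the average spacing between the cone and
#' its Delaunay neighbours; the Gaussian full width at half maximum is set
#' equal to that diameter (`sigma = diameter / (2 sqrt(2 ln 2))`, exposed as
#' `fwhm_factor`).
#'
#' @param mosaic A [cone_mosaic()].
#' @param patches Its [tessellate()] result (supplies neighbours and Voronoi
#'   areas).
#' @param diameter_fraction Aperture diameter as a fraction of mean neighbour
#'   spacing (default 0.48).
#' @param fwhm_factor Diameter-to-sigma conversion, `sigma = diameter /
#'   fwhm_factor` (default `2 sqrt(2 ln 2)` = 2.3548, i.e. FWHM = diameter).
#' @return Object of class `cone_apertures`: list with `x`, `y`, `diameter`
#'   (arcmin), `sigma` (arcmin), `area` (Voronoi patch, arcmin^2), `mosaic`.
#' @export
build_apertures <- function(mosaic, patches, diameter_fraction = 0.48,
                            fwhm_factor = 2 * sqrt(2 * log(2))) {
  stopifnot(inherits(mosaic, "cone_mosaic"), inherits(patches, "voronoi_patches"))
  spacing <- vapply(seq_len(mosaic$n), function(i) {
    nb <- patches$neighbors[[i]]
    if (!length(nb)) stop("cone ", i, " has no Delaunay neighbours")
    mean(sqrt((mosaic$x[nb] - mosaic$x[i])^2 + (mosaic$y[nb] - mosaic$y[i])^2))
  }, numeric(1))
  d <- diameter_fraction * spacing
  structure(list(x = mosaic$x, y = mosaic$y, diameter = d,
                 sigma = d / fwhm_factor, area = patches$area,
                 mosaic = mosaic),
            class = "cone_apertures")
}

#' @export
print.cone_apertures <- function(x, ...) {
  cat(sprintf("<cone_apertures> %d cones, diameter %.3f-%.3f arcmin (mean %.3f)\n",
              length(x$x), min(x$diameter), max(x$diameter), mean(x$diameter)))
  invisible(x)
}

## clamped bilinear interpolation; values outside the matrix are 0
.interp2 <- function(m, r, c) {
  out <- numeric(length(r))
  ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nrow(m) - 1); c0 <- pmin(floor(c), ncol(m) - 1)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
       (1 - fr) * fc       * m[cbind(r0, c0 + 1)] +
       fr       * (1 - fc) * m[cbind(r0 + 1, c0)] +
       fr       * fc       * m[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v
  out
}

#' Per-frame cone activation pattern
#'
#' Samples the retinal decrement image through every cone's Gaussian
#' aperture: activation is the aperture-weighted mean decrement, i.e. the
#' aperture integral of profile x image divided by the profile integral.
#' It is 1 when the aperture is entirely filled by full stimulus darkness and
#' 0 with no stimulus, and invariant to rescaling the aperture profile.
#'
#' @param apertures A [build_apertures()] result.
#' @param image A [retinal_image()].
#' @param stimulus_position Stimulus-center position `c(x, y)` in the mosaic
#'   frame (arcmin).
#' @param time_ms Optional frame time stamp carried through.
#' @param supersample Aperture integration grid oversampling relative to the
#'   image pixel scale (default 4).
#' @param sigma_span Integration radius in aperture sigmas (default 3).
#' @return Object of class `activation_pattern`: list with `activation`
#'   (numeric per cone, in `[0, 1]`), `time_ms`, `stimulus_position`.
#' @export
activation_pattern <- function(apertures, image, stimulus_position,
                               time_ms = NA_real_, supersample = 4,
                               sigma_span = 3) {
  stopifnot(inherits(apertures, "cone_apertures"), inherits(image, "retinal_image"))
  ext <- apertures$mosaic$extent
  sx <- stimulus_position[[1]]; sy <- stimulus_position[[2]]
  if (sx < 0 || sx > ext[1] || sy < 0 || sy > ext[2])
    stop("stimulus position lies outside the mosaic image extent")
  ps <- image$pixel_scale
  dec <- image$decrement
  ## image footprint in mosaic coordinates
  half_h <- nrow(dec) / 2 * ps; half_w <- ncol(dec) / 2 * ps
  act <- numeric(length(apertures$x))
  reach <- sigma_span * apertures$sigma
  near <- which(abs(apertures$x - sx) <= half_w + reach &
                abs(apertures$y - sy) <= half_h + reach)
  step <- ps / supersample
  for (i in near) {
    s <- apertures$sigma[i]
    g <- seq(-sigma_span * s, sigma_span * s, by = step)
    px <- apertures$x[i] + rep(g, times = length(g))
    py <- apertures$y[i] + rep(g, each = length(g))
    w <- exp(-(rep(g, times = length(g))^2 + rep(g, each = length(g))^2) /
               (2 * s^2))
    rr <- image$center["row"] + (py - sy) / ps
    cc <- image$center["col"] + (px - sx) / ps
    act[i] <- sum(w * .interp2(dec, rr, cc)) / sum(w)
  }
  structure(list(activation = pmin(pmax(act, 0), 1), time_ms = time_ms,
                 stimulus_position = c(x = sx, y = sy)),
            class = "activation_pattern")
}

#' Sampling cone density of one activation frame
#'
#' The number of cones identified to interact with the stimulus (activation
#' above `threshold`) divided by their summed Voronoi cone areas, in
#' cones/deg^2. With no interacting cone the frame is flagged undefined
#' (`NA` density) rather than silently zero.
#'
#' @param pattern An [activation_pattern()].
#' @param apertures The matching [build_apertures()] result.
#' @param threshold Interaction threshold on activation (default 0.01).
#' @return List with `density` (cones/deg^2 or `NA`), `n_interacting`,
#'   `undefined` (logical).
#' @export
sampling_cone_density <- function(pattern, apertures, threshold = 0.01) {
  stopifnot(inherits(pattern, "activation_pattern"),
            inherits(apertures, "cone_apertures"))
  sel <- pattern$activation > threshold
  n <- sum(sel)
  if (n == 0)
    return(list(density = NA_real_, n_interacting = 0L, undefined = TRUE))
  list(density = n / sum(apertures$area[sel]) * 3600,
       n_interacting = as.integer(n), undefined = FALSE)
}

#' Sampling-density series over one trial
#'
#' Evaluates the cone activation pattern and sampling cone density at every
#' trace sample inside the stimulus-on window. The trial's scalar summary is
#' the median over defined frames.
#'
#' @param apertures A [build_apertures()] result.
#' @param image The trial's [retinal_image()].
#' @param trace A [gaze_trace()] giving the stimulus-center trajectory in the
#'   mosaic frame.
#' @param threshold Interaction threshold (default 0.01).
#' @param ... Passed to [activation_pattern()].
#' @return Object of class `sampling_series`: list with `frames` (data.frame
#'   `t_ms, x, y, n_interacting, density, undefined`), `median_density`,
#'   `onset_density`.
#' @export
trial_sampling_series <- function(apertures, image, trace, threshold = 0.01,
                                  ...) {
  stopifnot(inherits(trace, "gaze_trace"))
  w <- trace$window
  sel <- trace$t_ms >= w[1] & trace$t_ms <= w[2]
  if (!any(sel)) stop("no trace samples inside the stimulus-on window")
  idx <- which(sel)
  rows <- lapply(idx, function(i) {
    pat <- activation_pattern(apertures, image,
                              c(trace$x[i], trace$y[i]),
                              time_ms = trace$t_ms[i], ...)
    scd <- sampling_cone_density(pat, apertures, threshold)
    data.frame(t_ms = trace$t_ms[i], x = trace$x[i], y = trace$y[i],
               n_interacting = scd$n_interacting, density = scd$density,
               undefined = scd$undefined)
  })
  frames <- do.call(rbind, rows)
  defined <- frames$density[!frames$undefined]
  structure(list(frames = frames,
                 median_density = if (length(defined)) stats::median(defined) else NA_real_,
                 onset_density = frames$density[1]),
            class = "sampling_series")
}

#' @export
print.sampling_series <- function(x, ...) {
  cat(sprintf("<sampling_series> %d frames, median %.0f cones/deg^2 (onset %.0f)\n",
              nrow(x$frames), x$median_density, x$onset_density))
  invisible(x)
}
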