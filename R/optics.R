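#' Optical configuration
#'
#' Imaging/stimulation optics for the diffraction-limited retinal-image
#' model: wavelength, pupil diameter, and raster pixel scale.
#'
#' @param wavelength_nm Wavelength in nm (default 788; must lie in
#'   400-1000 nm).
#' @param pupil_mm Pupil diameter in mm (default 7).
#' @param pixel_scale Arcmin per raster pixel (default 0.1).
#' @return Object of class `optical_config`.
#' @export
optical_config <- function(wavelength_nm = 788, pupil_mm = 7,
                           pixel_scale = 0.1) {
  stopifnot(wavelength_nm > 0, pupil_mm > 0, pixel_scale > 0)
  if (wavelength_nm < 400 || wavelength_nm > 1000)
    stop("wavelength must be in [400, 1000] nm")
  structure(list(wavelength_nm = wavelength_nm, pupil_mm = pupil_mm,
                 pixel_scale = pixel_scale),
            class = "optical_config")
}

## radians per arcmin
.ARCMIN <- pi / (180 * 60)

## dimensionless radius v enclosing `frac` of the Airy pattern's energy;
## encircled energy E(v) = 1 - J0(v)^2 - J1(v)^2
.airy_ee_radius <- function(frac) {
  stats::uniroot(function(v) 1 - besselJ(v, 0)^2 - besselJ(v, 1)^2 - frac,
                 c(1, 1e4), tol = 1e-6)$root
}

#' Airy-disk radius and diameter
#'
#' Radius (center to first intensity zero) of the diffraction pattern,
#' `1.22 * lambda / D`, and its diameter (first dark ring), in arcsec.
#'
#' @param config An [optical_config()].
#' @return Arcsec.
#' @examples
#' airy_disk_diameter(optical_config(788, 7))  # ~56.7 arcsec
#' @export
airy_disk_radius <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  1.22 * (config$wavelength_nm * 1e-9) / (config$pupil_mm * 1e-3) *
    (180 / pi) * 3600
}

#' @rdname airy_disk_radius
#' @export
airy_disk_diameter <- function(config) 2 * airy_disk_radius(config)

#' Diffraction-limited point spread function
#'
#' Rotationally symmetric Airy intensity pattern `[2 J1(v)/v]^2` sampled at
#' the raster pixel scale and normalized to unit sum. The kernel is a square
#' of side `2 * support_px + 1` pixels; by default `support_px` is the
#' smallest radius enclosing 99% of the Airy pattern's energy (from the
#' analytic encircled-energy curve `1 - J0(v)^2 - J1(v)^2`), about 17
#' first-zero radii. A support below 4 Airy radii is refused.
#'
#' @param config An [optical_config()].
#' @param support_px Kernel half-width in pixels (default: 99%
#'   encircled-energy radius).
#' @return Normalized square matrix of odd dimension with attributes
#'   `pixel_scale` and `config`.
#' @export
airy_psf <- function(config, support_px = NULL) {
  stopifnot(inherits(config, "optical_config"))
  r0_px <- airy_disk_radius(config) / 60 / config$pixel_scale
  if (is.null(support_px))
    support_px <- ceiling(.airy_ee_radius(0.99) / 3.831706 * r0_px)
  min_px <- ceiling(4 * r0_px)
  if (support_px < min_px)
    stop(sprintf(paste0("PSF support of %d px spans fewer than 4 Airy radii; ",
                        "need at least %d px at this pixel scale"),
                 support_px, min_px))
  off <- seq(-support_px, support_px) * config$pixel_scale
  rad <- sqrt(outer(off^2, off^2, "+")) * .ARCMIN
  v <- pi * (config$pupil_mm * 1e-3) * rad / (config$wavelength_nm * 1e-9)
  k <- ifelse(v < 1e-9, 1, (2 * besselJ(v, 1) / v)^2)
  k <- k / sum(k)
  attr(k, "pixel_scale") <- config$pixel_scale
  attr(k, "config") <- config
  k
}

#' Snellen-E stimulus specification
#'
#' Standard 5x5-unit Snellen E: stroke and gap width both equal one fifth of
#' letter height. `orientation` is the direction the three bars point
#' (i.e. the open side of the E); it is the 4AFC response variable.
#'
#' @param gap_arcsec Gap/stroke width in arcsec.
#' @param orientation One of `"up"`, `"down"`, `"left"`, `"right"`.
#' @return Object of class `stimulus_spec` (dark decrement stimulus).
#' @export
stimulus_spec <- function(gap_arcsec, orientation = "right") {
  stopifnot(is.numeric(gap_arcsec), gap_arcsec > 0)
  orientation <- match.arg(orientation, c("up", "down", "left", "right"))
  structure(list(gap_arcsec = gap_arcsec, orientation = orientation,
                 polarity = "decrement"),
            class = "stimulus_spec")
}

#' Render a Snellen-E bitmap
#'
#' Renders the 5x5-construction Snellen E as a binary decrement bitmap (1 in
#' strokes, 0 elsewhere) at the raster pixel scale. The gap width is
#' quantized to whole pixels; sub-pixel gaps are an error.
#'
#' @param spec A [stimulus_spec()] (or a gap size in arcsec).
#' @param pixel_scale Arcmin per pixel (default 0.1).
#' @return Binary matrix of side `5 * gap_px` with attributes `pixel_scale`,
#'   `gap_px` and `orientation`.
#' @examples
#' dim(make_snellen_e(stimulus_spec(18), 0.1))  # 15 x 15 px
#' @export
make_snellen_e <- function(spec, pixel_scale = 0.1) {
  if (is.numeric(spec)) spec <- stimulus_spec(spec)
  stopifnot(inherits(spec, "stimulus_spec"))
  u <- round(spec$gap_arcsec / 60 / pixel_scale)
  if (u < 1)
    stop(sprintf("gap of %.3g arcsec is below one pixel (%.3g arcsec) at this scale",
                 spec$gap_arcsec, pixel_scale * 60))
  n <- 5 * u
  m <- matrix(0, n, n)
  m[, seq_len(u)] <- 1                      # spine (left column)
  m[seq_len(u), ] <- 1                      # top bar
  m[(2 * u + 1):(3 * u), ] <- 1             # middle bar
  m[(4 * u + 1):(5 * u), ] <- 1             # bottom bar
  ## base letter opens rightward; rotate for the other orientations
  m <- switch(spec$orientation,
              right = m,
              up    = .rot90(m),            # bars point up
              left  = .rot90(.rot90(m)),
              down  = .rot90(.rot90(.rot90(m))))
  attr(m, "pixel_scale") <- pixel_scale
  attr(m, "gap_px") <- u
  attr(m, "orientation") <- spec$orientation
  m
}

## counterclockwise quarter turn in screen coordinates (y down)
.rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

## exact zero-padded linear convolution via FFT, same-size "center" crop
.conv2 <- function(img, kern) {
  ni <- dim(img); nk <- dim(kern)
  n <- ni + nk - 1
  pad <- function(m) {
    o <- matrix(0, n[1], n[2]); o[seq_len(nrow(m)), seq_len(ncol(m))] <- m; o
  }
  full <- Re(stats::fft(stats::fft(pad(img)) * stats::fft(pad(kern)),
                        inverse = TRUE)) / prod(n)
  off <- (nk - 1) / 2
  full[(1 + off[1]):(off[1] + ni[1]), (1 + off[2]):(off[2] + ni[2])]
}

#' Diffraction-limited retinal image of a stimulus
#'
#' Convolves a binary decrement bitmap with a normalized PSF. Working in
#' decrement space (background = 0, full stimulus darkness = 1) makes the
#' zero-padded convolution boundary the physically correct "background
#' continues" condition. The bitmap is padded by the PSF support so that no
#' blurred energy is clipped.
#'
#' @param bitmap Binary stimulus bitmap from [make_snellen_e()] (or any
#'   matrix in `[0, 1]` with a `pixel_scale` attribute).
#' @param psf Normalized kernel from [airy_psf()] at the same pixel scale.
#' @return Object of class `retinal_image`: list with `decrement` (matrix in
#'   `[0, 1]`), `pixel_scale`, and `center` (stimulus-center pixel indices,
#'   row/col).
#' @export
retinal_image <- function(bitmap, psf) {
  ps_b <- attr(bitmap, "pixel_scale"); ps_k <- attr(psf, "pixel_scale")
  if (is.null(ps_b) || is.null(ps_k) || abs(ps_b - ps_k) > 1e-12)
    stop("bitmap and PSF pixel scales do not match")
  if (abs(sum(psf) - 1) > 1e-6) stop("PSF must be normalized to unit sum")
  if (any(bitmap < 0 | bitmap > 1)) stop("bitmap values must lie in [0, 1]")
  pad <- (nrow(psf) - 1) / 2
  img <- matrix(0, nrow(bitmap) + 2 * pad, ncol(bitmap) + 2 * pad)
  img[pad + seq_len(nrow(bitmap)), pad + seq_len(ncol(bitmap))] <- bitmap
  dec <- .conv2(img, psf)
  dec[dec < 0] <- 0   # clip FFT ringing at ~1e-16
  dec[dec > 1] <- 1
  structure(list(decrement = dec, pixel_scale = ps_b,
                 center = c(row = pad + (nrow(bitmap) + 1) / 2,
                            col = pad + (ncol(bitmap) + 1) / 2)),
            class = "retinal_image")
}

#' @export
print.retinal_image <- function(x, ...) {
  cat(sprintf("<retinal_image> %d x %d px at %.3g arcmin/px, max decrement %.3f\n",
              nrow(x$decrement), ncol(x$decrement), x$pixel_scale,
              max(x$decrement)))
  invisible(x)
}

#' Stimulus contrast of a retinal image
#'
#' Contrast of the blurred dark stimulus against the uniform background
#' raster. With background intensity `I_bg = 1` and deepest stimulus trough
#' `I_min = 1 - max(decrement)`:
#'
#' * `"michelson"` (default): `(I_bg - I_min) / (I_bg + I_min)`, i.e.
#'   `d / (2 - d)` with `d` the maximum decrement. This metric reproduces the
#'   0.61 / 0.80 contrast pair for 18 / 36 arcsec gap stimuli under 788 nm,
#'   7 mm pupil optics.
#' * `"weber"`: `(I_bg - I_min) / I_bg = d`, the maximum decrement itself.
#'
#' @param image A [retinal_image()].
#' @param metric `"michelson"` or `"weber"`.
#' @return Contrast in `[0, 1]`.
#' @export
stimulus_contrast <- function(image, metric = c("michelson", "weber")) {
  stopifnot(inherits(image, "retinal_image"))
  metric <- match.arg(metric)
  d <- max(image$decrement)
  switch(metric, michelson = d / (2 - d), weber = d)
}
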