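#' Read and write cone-center tables
#'
#' Cone CSVs carry either pixel columns `x_px,y_px` (converted with the
#' config's `pixel_scale_arcmin`) or arcmin columns `x_arcmin,y_arcmin`.
#' Files with both dialects, or with neither, are refused rather than
#' guessed.
#'
#' @param path CSV path.
#' @param pixel_scale Arcmin per pixel, required for pixel-unit files.
#' @param extent Image extent in arcmin; default from the coordinate range
#'   rounded up to whole pixels.
#' @return [read_cone_csv()]: a [cone_mosaic()]. [write_cone_csv()]: the
#'   path, invisibly (coordinates written in arcmin).
#' @export
read_cone_csv <- function(path, pixel_scale = 0.1, extent = NULL) {
  d <- utils::read.csv(path)
  has_px <- all(c("x_px", "y_px") %in% names(d))
  has_am <- all(c("x_arcmin", "y_arcmin") %in% names(d))
  if (has_px && has_am)
    stop("ambiguous units in ", path, ": both _px and _arcmin columns present")
  if (!has_px && !has_am)
    stop("missing coordinate columns in ", path,
         ": need x_px,y_px or x_arcmin,y_arcmin")
  bad <- which(!stats::complete.cases(d))
  if (length(bad))
    stop("malformed rows in ", path, " at line(s) ",
         paste(bad + 1, collapse = ", "))
  if (has_px) {
    x <- d$x_px * pixel_scale; y <- d$y_px * pixel_scale
  } else {
    x <- d$x_arcmin; y <- d$y_arcmin
  }
  if (is.null(extent))
    extent <- ceiling(c(max(x), max(y)) / pixel_scale) * pixel_scale
  cone_mosaic(x, y, extent = extent, pixel_scale = pixel_scale)
}

#' @rdname read_cone_csv
#' @param mosaic A [cone_mosaic()].
#' @export
write_cone_csv <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  utils::write.csv(data.frame(x_arcmin = mosaic$x, y_arcmin = mosaic$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write gaze-trace tables
#'
#' Trace CSVs use columns `trial,frame,t_ms,x_arcmin,y_arcmin`. Reading
#' returns one [gaze_trace()] per trial; missing frames (gaps larger than
#' 1.5 nominal frame intervals) are reported via the `gaps` attribute.
#'
#' @param path CSV path.
#' @param window Stimulus-on window passed to [gaze_trace()].
#' @param frame_rate_hz Nominal frame rate (default 30).
#' @return [read_trace_csv()]: named list of [gaze_trace()] objects.
#'   [write_trace_csv()]: the path, invisibly.
#' @export
read_trace_csv <- function(path, window = c(0, 500), frame_rate_hz = 30) {
  d <- utils::read.csv(path)
  need <- c("trial", "frame", "t_ms", "x_arcmin", "y_arcmin")
  if (!all(need %in% names(d)))
    stop("trace CSV ", path, " missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(!stats::complete.cases(d[need]))
  if (length(bad))
    stop("malformed rows in ", path, " at line(s) ",
         paste(bad + 1, collapse = ", "))
  dt <- 1000 / frame_rate_hz
  out <- lapply(split(d, d$trial), function(tr) {
    tr <- tr[order(tr$t_ms), ]
    if (any(diff(tr$t_ms) <= 0))
      stop("non-monotone time in trial ", tr$trial[1], " of ", path)
    w <- c(max(window[1], tr$t_ms[1]), min(window[2], tr$t_ms[nrow(tr)]))
    g <- gaze_trace(tr$t_ms, tr$x_arcmin, tr$y_arcmin, trial = tr$trial[1],
                    window = w, frame_rate_hz = frame_rate_hz)
    gaps <- which(diff(tr$t_ms) > 1.5 * dt)
    attr(g, "gaps") <- if (length(gaps)) tr$t_ms[gaps] else numeric(0)
    g
  })
  out
}

#' @rdname read_trace_csv
#' @param traces A list of [gaze_trace()] objects (or a single one).
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "gaze_trace")) traces <- list(traces)
  rows <- lapply(traces, function(g)
    data.frame(trial = g$trial, frame = seq_along(g$t_ms), t_ms = g$t_ms,
               x_arcmin = g$x, y_arcmin = g$y))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write psychophysical trial tables
#'
#' Columns: `run,trial,gap_arcsec,orientation,response,correct`.
#'
#' @param path CSV path.
#' @return [read_trials_csv()]: data.frame. [write_trials_csv()]: the path,
#'   invisibly.
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("run", "trial", "gap_arcsec", "orientation", "response", "correct")
  if (!all(need %in% names(d)))
    stop("trials CSV ", path, " missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d$correct <- as.logical(d$correct)
  mism <- which(d$correct != (d$orientation == d$response))
  if (length(mism))
    stop("inconsistent correct flag in ", path, " at line(s) ",
         paste(mism + 1, collapse = ", "))
  d
}

#' @rdname read_trials_csv
#' @param trials data.frame of trial records.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Write landmark JSON
#'
#' Serializes a [foveolar_landmarks()] object (positions in arcmin,
#' densities in cones/deg^2, Nyquist in both arcmin and arcsec).
#'
#' @param landmarks A [foveolar_landmarks()].
#' @param path Output path.
#' @export
write_landmarks_json <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "foveolar_landmarks"))
  obj <- list(
    pcd = list(x = landmarks$pcd$location[["x"]],
               y = landmarks$pcd$location[["y"]],
               density = landmarks$pcd$value),
    cdc = list(x = landmarks$cdc[["x"]], y = landmarks$cdc[["y"]],
               density = landmarks$cdc_density),
    prl = if (is.null(landmarks$prl)) NULL else
      list(x = landmarks$prl[["x"]], y = landmarks$prl[["y"]]),
    icd_arcmin = landmarks$icd_arcmin,
    nyquist_arcmin = landmarks$nyquist_arcmin,
    nyquist_arcsec = landmarks$nyquist_arcsec,
    units = list(position = "arcmin", density = "cones/deg^2"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- list(
    pcd = list(location = c(x = obj$pcd$x, y = obj$pcd$y),
               value = obj$pcd$density, degenerate_tie = FALSE),
    cdc = c(x = obj$cdc$x, y = obj$cdc$y),
    prl = if (is.null(obj$prl)) NULL else c(x = obj$prl$x, y = obj$prl$y),
    cdc_density = obj$cdc$density,
    icd_arcmin = obj$icd_arcmin,
    nyquist_arcmin = obj$nyquist_arcmin,
    nyquist_arcsec = obj$nyquist_arcsec)
  class(lm) <- "foveolar_landmarks"
  lm
}

#' Write a density map as 32-bit TIFF or CSV
#'
#' The CSV stores densities in cones/deg^2. The 32-bit float TIFF stores
#' `density * 1e-5` (TIFF sample values must lie in `[0, 1]`; foveolar
#' densities are well below 1e5 cones/deg^2), so multiply by 1e5 when
#' reading back.
#'
#' @param map A [density_map()].
#' @param path Output path (`.tif`/`.tiff` or `.csv`).
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(map$values, path, row.names = FALSE)
  } else {
    tiff::writeTIFF(map$values * 1e-5, path,
                    bits.per.sample = 32, reduce = FALSE)
  }
  invisible(path)
}

#' Write a stimulus bitmap as PNG
#'
#' @param bitmap Binary matrix from [make_snellen_e()].
#' @param path Output path.
#' @export
write_stimulus_png <- function(bitmap, path) {
  png::writePNG(1 - bitmap, path)   # dark stimulus on bright background
  invisible(path)
}

#' Session configuration
#'
#' Bundles the acquisition geometry used across the pipeline. Defaults match
#' a 512 x 512 px AOSLO raster at 30 Hz spanning 0.85 x 0.85 deg (about 600
#' px/deg, 0.1 arcmin/px) stabilized in 32 strips per frame.
#'
#' @param pixel_scale_arcmin Arcmin per pixel (default 0.1).
#' @param field_deg Field size in degrees (default `c(0.85, 0.85)`).
#' @param field_px Raster size in pixels (default `c(512, 512)`).
#' @param frame_rate_hz Video frame rate (default 30).
#' @param strips_per_frame Stabilization strips per frame (default 32).
#' @param wavelength_nm Imaging/stimulation wavelength (default 788).
#' @param pupil_mm Pupil diameter (default 7).
#' @param declared_px_per_deg Nominal pixels/deg to check against
#'   (default 600).
#' @param declared_strip_rate_hz Nominal strip-level trace rate to check
#'   against (default 960).
#' @return Object of class `session_config`.
#' @export
session_config <- function(pixel_scale_arcmin = 0.1,
                           field_deg = c(0.85, 0.85),
                           field_px = c(512, 512),
                           frame_rate_hz = 30, strips_per_frame = 32,
                           wavelength_nm = 788, pupil_mm = 7,
                           declared_px_per_deg = 600,
                           declared_strip_rate_hz = 960) {
  structure(list(pixel_scale_arcmin = pixel_scale_arcmin,
                 field_deg = field_deg, field_px = field_px,
                 frame_rate_hz = frame_rate_hz,
                 strips_per_frame = strips_per_frame,
                 wavelength_nm = wavelength_nm, pupil_mm = pupil_mm,
                 declared_px_per_deg = declared_px_per_deg,
                 declared_strip_rate_hz = declared_strip_rate_hz),
            class = "session_config")
}

#' Read a session configuration from YAML or JSON
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A [session_config()].
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(session_config, lst[intersect(names(lst),
                                        names(formals(session_config)))])
}

#' Configuration consistency report
#'
#' Recomputes derived acquisition quantities and compares them with the
#' declared values: strip-level trace rate (`frame_rate * strips_per_frame`)
#' and raster resolution in px/deg (both from the pixel scale and from
#' `field_px / field_deg`).
#'
#' @param config A [session_config()].
#' @param tol Relative tolerance before a value is flagged (default 0.01).
#' @return List with `strip_rate_hz`, `px_per_deg`, `px_per_deg_from_field`,
#'   and a data.frame `checks` (`quantity`, `derived`, `declared`, `ok`).
#' @export
config_consistency <- function(config, tol = 0.01) {
  stopifnot(inherits(config, "session_config"))
  strip_rate <- config$frame_rate_hz * config$strips_per_frame
  ppd <- 60 / config$pixel_scale_arcmin
  ppd_field <- config$field_px[1] / config$field_deg[1]
  checks <- data.frame(
    quantity = c("strip_rate_hz", "px_per_deg", "px_per_deg_from_field"),
    derived = c(strip_rate, ppd, ppd_field),
    declared = c(config$declared_strip_rate_hz, config$declared_px_per_deg,
                 config$declared_px_per_deg),
    stringsAsFactors = FALSE)
  checks$ok <- abs(checks$derived - checks$declared) <=
    tol * abs(checks$declared)
  for (i in which(!checks$ok))
    warning(sprintf("config inconsistency: %s derived %.6g vs declared %.6g",
                    checks$quantity[i], checks$derived[i], checks$declared[i]))
  list(strip_rate_hz = strip_rate, px_per_deg = ppd,
       px_per_deg_from_field = ppd_field, checks = checks)
}
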