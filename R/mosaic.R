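#' Cone mosaic object
#'
#' Bundle labelled cone-center coordinates with the calibrated image geometry
#' they live on. Coordinates are in arcmin in the image frame: origin at the
#' top-left image corner, x increasing rightward, y increasing downward
#' (1 deg = 60 arcmin).
#'
#' @param x,y Numeric vectors of cone-center coordinates (arcmin).
#' @param extent Numeric length-2, image width and height in arcmin.
#' @param pixel_scale Arcmin per image pixel (default 0.1, i.e. 600 px/deg).
#' @return An object of class `cone_mosaic`: a list with `x`, `y`, `extent`,
#'   `pixel_scale` and `n` (number of cones).
#' @examples
#' m <- cone_mosaic(c(1, 2, 1, 2), c(1, 1, 2, 2), extent = c(3, 3))
#' m$n
#' @export
cone_mosaic <- function(x, y, extent, pixel_scale = 0.1) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (!is.numeric(extent) || length(extent) != 2 || any(extent <= 0))
    stop("`extent` must be positive width and height in arcmin")
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1 || pixel_scale <= 0)
    stop("`pixel_scale` must be a positive scalar (arcmin/px)")
  if (anyNA(x) || anyNA(y)) stop("cone coordinates contain NA")
  if (any(x < 0 | x > extent[1] | y < 0 | y > extent[2]))
    stop("all cone centers must lie inside the image extent")
  if (anyDuplicated(cbind(x, y)))
    stop("duplicate cone centers found; no two centers may coincide")
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         extent = as.numeric(extent), pixel_scale = pixel_scale,
         n = length(x)),
    class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("<cone_mosaic> %d cones on %.2f x %.2f arcmin (%.3g arcmin/px)\n",
              x$n, x$extent[1], x$extent[2], x$pixel_scale))
  invisible(x)
}

#' Voronoi tessellation of a cone mosaic
#'
#' Computes the Voronoi patch (polygon area) of every cone, clipped to the
#' image rectangle, plus the Delaunay neighbour relation. Boundary cells are
#' flagged `clipped` when they touch the image edge; their areas are the
#' clipped polygon areas, so the sum of all patch areas equals the image area.
#'
#' @param mosaic A [cone_mosaic()].
#' @return An object of class `voronoi_patches`: list with `area` (arcmin^2
#'   per cone), `neighbors` (list of integer vectors, Delaunay-adjacent cone
#'   indices), `clipped` (logical per cone), and `mosaic`.
#' @export
tessellate <- function(mosaic) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  if (mosaic$n < 4)
    stop("tessellation requires at least 4 cone centers (got ", mosaic$n, ")")
  ## degenerate (collinear) input has zero spread orthogonal to the best line
  xy <- cbind(mosaic$x, mosaic$y)
  sv <- svd(scale(xy, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("tessellation error: cone centers are collinear")
  dd <- deldir::deldir(mosaic$x, mosaic$y,
                       rw = c(0, mosaic$extent[1], 0, mosaic$extent[2]),
                       suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  area <- vapply(unname(tl), function(t) {
    ## shoelace on the clipped tile polygon
    px <- t$x; py <- t$y
    abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  }, numeric(1))
  eps <- 1e-9
  clipped <- vapply(tl, function(t) {
    any(t$x < eps | t$x > mosaic$extent[1] - eps |
        t$y < eps | t$y > mosaic$extent[2] - eps)
  }, logical(1))
  nb <- vector("list", mosaic$n)
  for (i in seq_len(nrow(dd$delsgs))) {
    a <- dd$delsgs$ind1[i]; b <- dd$delsgs$ind2[i]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  structure(list(area = area, neighbors = nb, clipped = clipped,
                 mosaic = mosaic),
            class = "voronoi_patches")
}

#' @export
print.voronoi_patches <- function(x, ...) {
  cat(sprintf("<voronoi_patches> %d cells, %d clipped; area %.3f-%.3f arcmin^2\n",
              length(x$area), sum(x$clipped), min(x$area), max(x$area)))
  invisible(x)
}

#' Pixel-resolved cone-density map
#'
#' For every pixel center, sums the Voronoi patch areas of the `k` cones
#' nearest to it (Euclidean pixel-center-to-cone-center distance, ties broken
#' by cone index) and reports `k` divided by that summed area, converted to
#' cones/deg^2.
#'
#' For speed the map may be computed on a decimated grid (`stride` > 1);
#' landmark extractors refine on the full grid in a window around the coarse
#' optimum when given the originating mosaic.
#'
#' @param mosaic A [cone_mosaic()].
#' @param patches Its [tessellate()] result.
#' @param k Number of nearest cones to pool (default 150).
#' @param stride Grid decimation factor in pixels (default 1 = every pixel).
#' @param margin Optional edge margin in arcmin excluded from the grid
#'   (default 0).
#' @return Object of class `density_map`: list with `values` (matrix,
#'   rows = y, cols = x, cones/deg^2), `px_x`, `px_y` (pixel-center
#'   coordinates, arcmin), `k`, `stride`, `pixel_scale`.
#' @export
density_map <- function(mosaic, patches, k = 150, stride = 1, margin = 0) {
  stopifnot(inherits(mosaic, "cone_mosaic"), inherits(patches, "voronoi_patches"))
  if (mosaic$n < k)
    stop("density_map needs at least k = ", k, " cones (mosaic has ",
         mosaic$n, "); use a smaller k")
  g <- .density_grid(mosaic, stride, margin)
  vals <- .knn_density(g$px_x, g$px_y, mosaic, patches$area, k)
  structure(list(values = vals, px_x = g$px_x, px_y = g$px_y, k = k,
                 stride = stride, margin = margin,
                 pixel_scale = mosaic$pixel_scale),
            class = "density_map")
}

.density_grid <- function(mosaic, stride, margin) {
  sc <- mosaic$pixel_scale
  nx <- floor(mosaic$extent[1] / sc)
  ny <- floor(mosaic$extent[2] / sc)
  px_x <- (seq(1, nx, by = stride) - 0.5) * sc
  px_y <- (seq(1, ny, by = stride) - 0.5) * sc
  if (margin > 0) {
    px_x <- px_x[px_x >= margin & px_x <= mosaic$extent[1] - margin]
    px_y <- px_y[px_y >= margin & px_y <= mosaic$extent[2] - margin]
  }
  if (!length(px_x) || !length(px_y)) stop("empty density grid")
  list(px_x = px_x, px_y = px_y)
}

## k-nearest-cone pooled density at arbitrary query points, cones/deg^2
.knn_density <- function(px_x, px_y, mosaic, areas, k) {
  q <- cbind(rep(px_x, each = length(px_y)), rep(px_y, times = length(px_x)))
  nn <- RANN::nn2(cbind(mosaic$x, mosaic$y), q, k = k)
  summed <- matrix(areas[nn$nn.idx], nrow = nrow(q))
  dens <- k / rowSums(summed) * 3600  # arcmin^-2 -> deg^-2
  matrix(dens, nrow = length(px_y), ncol = length(px_x))
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d grid (stride %d, k = %d), %.0f-%.0f cones/deg^2\n",
              nrow(x$values), ncol(x$values), x$stride, x$k,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Peak cone density (PCD)
#'
#' The maximum of the pixel-resolved density map and its location. Ties are
#' broken by the first maximal pixel in row-major order (left-to-right within
#' a row, rows top to bottom) and flagged as degenerate.
#'
#' @param map A [density_map()].
#' @return List with `location` (x, y arcmin), `value` (cones/deg^2) and
#'   `degenerate_tie` (logical).
#' @export
peak_cone_density <- function(map) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  mx <- max(v)
  hits <- which(t(v) == mx)  # transpose -> row-major order of the image
  j <- (hits[1] - 1) %% ncol(v) + 1
  i <- (hits[1] - 1) %/% ncol(v) + 1
  list(location = c(x = map$px_x[j], y = map$px_y[i]),
       value = mx,
       degenerate_tie = length(hits) > 1)
}

#' Cone density centroid (CDC)
#'
#' The density-weighted centroid of the highest-density pixels of the map:
#' pixels with density at or above the `1 - top_fraction` quantile of all map
#' values are selected and their pixel centers averaged with the density as
#' weight.
#'
#' @param map A [density_map()].
#' @param top_fraction Fraction of highest-density pixels to use
#'   (default 0.20).
#' @return Named numeric `c(x, y)` in arcmin.
#' @export
cone_density_centroid <- function(map, top_fraction = 0.20) {
  stopifnot(inherits(map, "density_map"),
            top_fraction > 0, top_fraction <= 1)
  v <- map$values
  thr <- stats::quantile(v, 1 - top_fraction, names = FALSE)
  sel <- v >= thr
  w <- v[sel]
  xs <- matrix(map$px_x, nrow = nrow(v), ncol = ncol(v), byrow = TRUE)[sel]
  ys <- matrix(map$px_y, nrow = nrow(v), ncol = ncol(v))[sel]
  c(x = sum(w * xs) / sum(w), y = sum(w * ys) / sum(w))
}

#' Inter-cone distance from density
#'
#' Average center-to-center spacing of a perfect hexagonal mosaic with the
#' given density: `ICD = sqrt(2 / (sqrt(3) * density))` with density per
#' deg^2, returned in arcmin.
#'
#' @param density Cone density in cones/deg^2 (vectorised).
#' @return ICD in arcmin.
#' @examples
#' icd_from_density(14255)  # ~0.540 arcmin
#' @export
icd_from_density <- function(density) {
  if (any(!is.finite(density)) || any(density <= 0))
    stop("density must be positive and finite")
  sqrt(2 / (sqrt(3) * density)) * 60
}

#' Nyquist sampling limit from inter-cone distance
#'
#' The finest resolvable detail implied by the spacing between rows of a
#' hexagonal cone lattice: `N = (sqrt(3)/2) * ICD`. The lattice constant is
#' exposed as an argument.
#'
#' @param icd Inter-cone distance in arcmin (vectorised).
#' @param row_spacing_factor Row-spacing constant (default `sqrt(3)/2`).
#' @return Nyquist limit in arcmin.
#' @export
nyquist_limit <- function(icd, row_spacing_factor = sqrt(3) / 2) {
  if (any(!is.finite(icd)) || any(icd <= 0)) stop("icd must be positive")
  row_spacing_factor * icd
}

#' Foveolar landmark set
#'
#' Derive the landmark bundle used by the drift and psychophysics stages from
#' a density map: PCD location/value, CDC location, ICD and Nyquist limit at
#' the CDC density, plus the externally supplied PRL.
#'
#' When `mosaic` and `patches` are given and the map was computed on a
#' decimated grid, PCD and CDC are refined on the full-resolution grid in a
#' window (`refine_window`, arcmin) around the coarse estimates.
#'
#' @param map A [density_map()].
#' @param prl Optional preferred retinal locus, numeric `c(x, y)` arcmin.
#' @param mosaic,patches Optional originals for full-resolution refinement.
#' @param top_fraction Passed to [cone_density_centroid()].
#' @param refine_window Half-width of the refinement window (default 2
#'   arcmin).
#' @return Object of class `foveolar_landmarks`: list with `pcd` (location +
#'   value), `cdc`, `prl`, `cdc_density`, `icd_arcmin`, `nyquist_arcmin`,
#'   `nyquist_arcsec`.
#' @export
foveolar_landmarks <- function(map, prl = NULL, mosaic = NULL, patches = NULL,
                               top_fraction = 0.20, refine_window = 2) {
  stopifnot(inherits(map, "density_map"))
  pcd <- peak_cone_density(map)
  cdc <- cone_density_centroid(map, top_fraction)
  if (map$stride > 1 && !is.null(mosaic) && !is.null(patches)) {
    pcd <- .refine_peak(pcd, mosaic, patches, map$k, refine_window)
  }
  cdc_density <- .density_at(cdc, map, mosaic, patches)
  icd <- icd_from_density(cdc_density)
  ny <- nyquist_limit(icd)
  structure(list(pcd = pcd, cdc = cdc,
                 prl = if (is.null(prl)) NULL else c(x = prl[[1]], y = prl[[2]]),
                 cdc_density = cdc_density,
                 icd_arcmin = icd,
                 nyquist_arcmin = ny, nyquist_arcsec = ny * 60),
            class = "foveolar_landmarks")
}

.refine_peak <- function(pcd, mosaic, patches, k, win) {
  sc <- mosaic$pixel_scale
  xr <- pmax(sc / 2, pcd$location["x"] + c(-win, win))
  yr <- pmax(sc / 2, pcd$location["y"] + c(-win, win))
  px_x <- seq(xr[1], min(xr[2], mosaic$extent[1]), by = sc)
  px_y <- seq(yr[1], min(yr[2], mosaic$extent[2]), by = sc)
  vals <- .knn_density(px_x, px_y, mosaic, patches$area, k)
  mx <- max(vals)
  hit <- which(t(vals) == mx)[1]
  j <- (hit - 1) %% ncol(vals) + 1
  i <- (hit - 1) %/% ncol(vals) + 1
  list(location = c(x = px_x[j], y = px_y[i]), value = mx,
       degenerate_tie = pcd$degenerate_tie)
}

## density-map value at an arbitrary point: exact nearest-k recomputation when
## the mosaic is available, nearest grid pixel otherwise
.density_at <- function(pt, map, mosaic = NULL, patches = NULL) {
  if (!is.null(mosaic) && !is.null(patches)) {
    as.numeric(.knn_density(pt[[1]], pt[[2]], mosaic, patches$area, map$k))
  } else {
    i <- which.min(abs(map$px_y - pt[[2]]))
    j <- which.min(abs(map$px_x - pt[[1]]))
    map$values[i, j]
  }
}

#' @export
print.foveolar_landmarks <- function(x, ...) {
  cat("<foveolar_landmarks>\n")
  cat(sprintf("  PCD: %.0f cones/deg^2 at (%.2f, %.2f) arcmin%s\n",
              x$pcd$value, x$pcd$location["x"], x$pcd$location["y"],
              if (isTRUE(x$pcd$degenerate_tie)) " [degenerate-tie]" else ""))
  cat(sprintf("  CDC: (%.2f, %.2f) arcmin, density %.0f cones/deg^2\n",
              x$cdc["x"], x$cdc["y"], x$cdc_density))
  if (!is.null(x$prl))
    cat(sprintf("  PRL: (%.2f, %.2f) arcmin\n", x$prl["x"], x$prl["y"]))
  cat(sprintf("  ICD %.3f arcmin; Nyquist %.3f arcmin (%.1f arcsec)\n",
              x$icd_arcmin, x$nyquist_arcmin, x$nyquist_arcsec))
  invisible(x)
}
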