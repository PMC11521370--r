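# Fixtures shared across test files; all built in code, nothing on disk.

# Reflection-symmetric hexagonal lattice strip. Rows sit at (i - 0.5) * dy so
# the top/bottom image edges cut between rows and clipped boundary cells keep
# (in sum) their fair share of area. The lateral edges cut through the
# staggered columns and cannot be boundary-fair, so closed-form density checks
# evaluate a central band at least `hex_pool_radius(k, s)` away from them.
hex_mosaic <- function(s = 0.54, ncol = 24, nrow = 26, pixel_scale = 0.1) {
  dy <- s * sqrt(3) / 2
  pts <- do.call(rbind, lapply(seq_len(nrow), function(i) {
    xs <- if (i %% 2 == 1) (seq_len(ncol) - 0.5) * s else seq_len(ncol - 1) * s
    cbind(xs, (i - 0.5) * dy)
  }))
  cone_mosaic(pts[, 1], pts[, 2], extent = c(ncol * s, nrow * dy),
              pixel_scale = pixel_scale)
}

# closed-form hexagonal lattice density, cones/deg^2
hex_density <- function(s) 2 / (sqrt(3) * s^2) * 3600

# radius (arcmin) of the disk holding the k nearest cones of a lattice
hex_pool_radius <- function(k, s) sqrt(k * sqrt(3) / 2 * s^2 / pi)

# independent exhaustive nearest-k density oracle (cones/deg^2)
brute_density <- function(mosaic, areas, qx, qy, k) {
  vapply(seq_along(qx), function(i) {
    d <- sqrt((mosaic$x - qx[i])^2 + (mosaic$y - qy[i])^2)
    k / sum(areas[order(d)[seq_len(k)]]) * 3600
  }, numeric(1))
}

# synthetic retinal image with a constant decrement everywhere
uniform_retinal_image <- function(value, n_row, n_col, pixel_scale = 0.1) {
  structure(list(decrement = matrix(value, n_row, n_col),
                 pixel_scale = pixel_scale,
                 center = c(row = (n_row + 1) / 2, col = (n_col + 1) / 2)),
            class = "retinal_image")
}

# bare density_map object on a given value matrix (whitebox landmark tests)
fake_density_map <- function(values, pixel_scale = 0.1, stride = 1) {
  structure(list(values = values,
                 px_x = (seq_len(ncol(values)) - 0.5) * pixel_scale * stride,
                 px_y = (seq_len(nrow(values)) - 0.5) * pixel_scale * stride,
                 k = 150, stride = stride, margin = 0,
                 pixel_scale = pixel_scale),
            class = "density_map")
}

# bare sampling_series object (whitebox gain tests)
fake_series <- function(densities, t_ms = seq_along(densities)) {
  structure(list(frames = data.frame(t_ms = t_ms, x = 0, y = 0,
                                     n_interacting = 1L, density = densities,
                                     undefined = !is.finite(densities)),
                 median_density = stats::median(densities, na.rm = TRUE),
                 onset_density = densities[1]),
            class = "sampling_series")
}
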