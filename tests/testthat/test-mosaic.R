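test_that("Voronoi patches have correct areas, symmetric neighbours, clip flags", {
  # 4 cones at the corners of a unit square centered in a 2x2 field:
  # symmetry forces four equal 1-arcmin^2 cells
  m <- cone_mosaic(c(0.5, 1.5, 0.5, 1.5), c(0.5, 0.5, 1.5, 1.5),
                   extent = c(2, 2))
  p <- tessellate(m)
  expect_equal(p$area, rep(1, 4), tolerance = 1e-9)
  expect_true(all(p$clipped))
  for (i in seq_len(4))
    for (j in p$neighbors[[i]])
      expect_true(i %in% p$neighbors[[j]])

  # interior cell of a perfect hexagonal lattice: area = (sqrt(3)/2) s^2
  s <- 0.54
  hm <- hex_mosaic(s)
  hp <- tessellate(hm)
  interior <- hm$x > 2 * s & hm$x < hm$extent[1] - 2 * s &
              hm$y > 2 * s & hm$y < hm$extent[2] - 2 * s
  expect_equal(hp$area[interior], rep(sqrt(3) / 2 * s^2, sum(interior)),
               tolerance = 1e-6)
  expect_false(any(hp$clipped[interior]))
  # cells partition the image: total area equals the field area
  expect_equal(sum(hp$area), prod(hm$extent), tolerance = 1e-6)
})

test_that("degenerate tessellation input is refused", {
  m3 <- cone_mosaic(c(1, 2, 3), c(1, 2, 3), extent = c(5, 5))
  expect_error(tessellate(m3), "at least 4")
  mc <- cone_mosaic(c(1, 2, 3, 4), c(1, 2, 3, 4), extent = c(5, 5))
  expect_error(tessellate(mc), "collinear")
  expect_error(cone_mosaic(c(1, 1), c(2, 2), extent = c(5, 5)), "coincide")
  expect_error(cone_mosaic(1, 7, extent = c(5, 5)), "inside")
})

test_that("nearest-k density matches the hexagonal closed form", {
  s <- 0.54
  m <- hex_mosaic(s)
  p <- tessellate(m)
  dm <- density_map(m, p, k = 150, stride = 2)
  truth <- hex_density(s)
  # central pixel
  jc <- which.min(abs(dm$px_x - m$extent[1] / 2))
  ic <- which.min(abs(dm$px_y - m$extent[2] / 2))
  expect_equal(dm$values[ic, jc], truth, tolerance = 1e-3)
  # all pixels >= 2s from the row-parallel boundaries, away from the
  # staggered lateral edges (see helper-fixtures.R)
  xm <- hex_pool_radius(150, s) + 2 * s
  X <- matrix(dm$px_x, nrow(dm$values), ncol(dm$values), byrow = TRUE)
  Y <- matrix(dm$px_y, nrow(dm$values), ncol(dm$values))
  band <- X >= xm & X <= m$extent[1] - xm &
          Y >= 2 * s & Y <= m$extent[2] - 2 * s
  expect_true(any(band))
  expect_lt(max(abs(dm$values[band] - truth) / truth), 0.005)
  # k-independence on a uniform lattice
  d7 <- foveolar:::.knn_density(m$extent[1] / 2, m$extent[2] / 2, m, p$area, 7)
  d150 <- foveolar:::.knn_density(m$extent[1] / 2, m$extent[2] / 2, m, p$area, 150)
  expect_equal(d7, d150, tolerance = 1e-3)
})

test_that("density matches an exhaustive brute-force oracle and scales correctly", {
  set.seed(42)
  m <- cone_mosaic(runif(250, 0, 10), runif(250, 0, 10), extent = c(10, 10))
  p <- tessellate(m)
  qx <- runif(25, 0, 10); qy <- runif(25, 0, 10)
  fast1 <- vapply(seq_along(qx),
                  function(i) foveolar:::.knn_density(qx[i], qy[i], m, p$area, 20),
                  numeric(1))
  expect_equal(fast1, brute_density(m, p$area, qx, qy, 20), tolerance = 1e-12)

  # doubling all coordinates divides every density by 4
  m2 <- cone_mosaic(m$x * 2, m$y * 2, extent = c(20, 20),
                    pixel_scale = m$pixel_scale * 2)
  p2 <- tessellate(m2)
  dm1 <- density_map(m, p, k = 20, stride = 10)
  dm2 <- density_map(m2, p2, k = 20, stride = 10)
  expect_equal(dm2$values, dm1$values / 4, tolerance = 1e-6)

  expect_error(density_map(m, p, k = 500), "smaller k")
})

test_that("adding cones never decreases density at an interior pixel", {
  set.seed(7)
  m <- cone_mosaic(runif(300, 0, 10), runif(300, 0, 10), extent = c(10, 10))
  p <- tessellate(m)
  d0 <- foveolar:::.knn_density(5, 5, m, p$area, 20)
  for (i in 1:5) {
    m2 <- cone_mosaic(c(m$x, runif(5, 4, 6)), c(m$y, runif(5, 4, 6)),
                      extent = c(10, 10))
    p2 <- tessellate(m2)
    d1 <- foveolar:::.knn_density(5, 5, m2, p2$area, 20)
    expect_gte(d1, d0 * (1 - 1e-9))
  }
})

test_that("PCD returns the row-major argmax with degenerate ties flagged", {
  v <- matrix(10000, 20, 30)
  v[13, 21] <- 12000
  dm <- fake_density_map(v)
  pcd <- peak_cone_density(dm)
  expect_equal(pcd$value, 12000)
  expect_equal(unname(pcd$location), c(dm$px_x[21], dm$px_y[13]))
  expect_false(pcd$degenerate_tie)

  flat <- fake_density_map(matrix(9000, 5, 5))
  pcd2 <- peak_cone_density(flat)
  expect_true(pcd2$degenerate_tie)
  expect_equal(unname(pcd2$location), c(flat$px_x[1], flat$px_y[1]))
})

test_that("CDC is the density-weighted centroid of the top pixels", {
  # uniform map: CDC at the geometric centroid of the grid
  flat <- fake_density_map(matrix(9000, 11, 17))
  cdc <- cone_density_centroid(flat)
  expect_equal(unname(cdc), c(mean(flat$px_x), mean(flat$px_y)),
               tolerance = 1e-12)
  # radially symmetric peak: CDC within one pixel of its center
  n <- 61
  cx <- (n + 1) / 2
  r2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+")
  bump <- fake_density_map(10000 + 5000 * exp(-r2 / 200))
  cdc2 <- cone_density_centroid(bump)
  expect_lt(abs(cdc2[["x"]] - bump$px_x[cx]), bump$pixel_scale)
  expect_lt(abs(cdc2[["y"]] - bump$px_y[cx]), bump$pixel_scale)
})

test_that("ICD and Nyquist closed forms give the field's canonical values", {
  expect_equal(icd_from_density(14255.56), 0.540, tolerance = 1e-4)
  expect_equal(icd_from_density(13640), 0.552, tolerance = 1e-3)
  # quadrupling density halves the spacing
  expect_equal(icd_from_density(4 * 12000), icd_from_density(12000) / 2)
  expect_equal(nyquist_limit(1), sqrt(3) / 2)
  expect_equal(nyquist_limit(icd_from_density(14255.56)) * 60, 28.06,
               tolerance = 1e-3)
  expect_equal(nyquist_limit(0.552) * 60, 28.68, tolerance = 1e-3)
  expect_error(icd_from_density(-1), "positive")
  expect_error(nyquist_limit(0), "positive")
})

test_that("landmarks recover the generator's density peak", {
  errs <- vapply(1:5, function(s) {
    gm <- generate_mosaic(mosaic_params(field_arcmin = c(20, 20)), seed = s)
    p <- tessellate(gm$mosaic)
    dm <- density_map(gm$mosaic, p, stride = 4)
    lm <- foveolar_landmarks(dm, prl = c(11, 11), mosaic = gm$mosaic,
                             patches = p)
    sqrt(sum((lm$cdc - gm$truth$peak)^2))
  }, numeric(1))
  expect_lt(median(errs), 1)
  # landmark bundle consistency on one mosaic
  gm <- generate_mosaic(mosaic_params(field_arcmin = c(20, 20)), seed = 99)
  p <- tessellate(gm$mosaic)
  dm <- density_map(gm$mosaic, p, stride = 4)
  lm <- foveolar_landmarks(dm, prl = c(11, 11), mosaic = gm$mosaic, patches = p)
  # full-grid refinement can only improve on the decimated-grid maximum
  expect_gte(lm$pcd$value, max(dm$values))
  expect_lt(lm$nyquist_arcmin, lm$icd_arcmin)
  expect_equal(lm$nyquist_arcsec, lm$nyquist_arcmin * 60)
})
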