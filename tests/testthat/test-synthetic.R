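test_that("a jitter-free, gradient-free mosaic reproduces its target density", {
  gm <- generate_mosaic(mosaic_params(gradient = 0, jitter = 0,
                                      field_arcmin = c(16, 16)), seed = 1)
  p <- tessellate(gm$mosaic)
  dm <- density_map(gm$mosaic, p, stride = 3)
  s <- sqrt(2 / (sqrt(3) * 14000 / 3600))
  xm <- hex_pool_radius(150, s) + 2 * s
  X <- matrix(dm$px_x, nrow(dm$values), ncol(dm$values), byrow = TRUE)
  Y <- matrix(dm$px_y, nrow(dm$values), ncol(dm$values))
  band <- X >= xm & X <= 16 - xm & Y >= xm & Y <= 16 - xm
  expect_lt(max(abs(dm$values[band] - 14000) / 14000), 0.005)
})

test_that("generators are reproducible from (params, seed)", {
  p <- mosaic_params(field_arcmin = c(14, 14))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cone_csv(generate_mosaic(p, seed = 5)$mosaic, f1)
  write_cone_csv(generate_mosaic(p, seed = 5)$mosaic, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- generate_drift_trace(drift_params(kappa = 1), start = c(5, 5),
                             target = c(8, 8), seed = 3)
  g2 <- generate_drift_trace(drift_params(kappa = 1), start = c(5, 5),
                             target = c(8, 8), seed = 3)
  expect_identical(g1$trace$x, g2$trace$x)
  s1 <- generate_session(mosaic_params(field_arcmin = c(18, 18)), seed = 4)
  s2 <- generate_session(mosaic_params(field_arcmin = c(18, 18)), seed = 4)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$truth$observer_alpha, s2$truth$observer_alpha)
})

test_that("drift traces hit the targeted path-length statistics", {
  set.seed(13)
  L <- replicate(400, drift_length(
    generate_drift_trace(drift_params(), start = c(0, 0))$trace)$length)
  expect_lt(abs(median(L) - 6.5) / 6.5, 0.10)
  # per-trial lognormal scale gives a wide but bounded spread
  expect_gt(stats::quantile(L, 0.99), 12)
  expect_lt(stats::quantile(L, 0.01), 4)
})

test_that("directional bias pulls trials toward the target and scales with kappa", {
  target <- c(10, 10)
  frac_nearer <- function(kappa, n, seed0) {
    mean(vapply(seq_len(n), function(i) {
      set.seed(seed0 + i)
      start <- c(runif(1, 2, 18), runif(1, 2, 18))
      g <- generate_drift_trace(drift_params(kappa = kappa), start = start,
                                target = target)
      idx <- which(g$trace$t_ms >= 300 & g$trace$t_ms <= 800)
      d0 <- sqrt(sum((c(g$trace$x[idx[1]], g$trace$y[idx[1]]) - target)^2))
      d1 <- sqrt(sum((c(g$trace$x[max(idx)], g$trace$y[max(idx)]) - target)^2))
      d1 < d0
    }, logical(1)))
  }
  expect_gt(frac_nearer(4, 200, 100), 0.6)
  tuning_at <- function(kappa, n, seed0) {
    th <- vapply(seq_len(n), function(i) {
      set.seed(seed0 + i)
      start <- c(runif(1, 4, 16), runif(1, 4, 16))
      g <- generate_drift_trace(drift_params(kappa = kappa), start = start,
                                target = target)
      angle_to_landmark(g$trace, target)
    }, numeric(1))
    tuning_ratio(th)
  }
  # ratio rises steeply over weak-to-moderate bias and saturates above:
  # near the ceiling the far-quadrant counts are tiny and the ratio noisy,
  # so strict ordering is only informative at the low end
  tr <- vapply(c(0, 0.5, 1, 2, 4), tuning_at, numeric(1), n = 500, seed0 = 900)
  expect_true(all(diff(tr[1:3]) > 0))
  expect_lt(abs(tr[1] - 1), 0.35)
  expect_true(all(tr[4:5] > tr[2]))
})

test_that("injected microsaccades are labelled and recovered", {
  hits <- vapply(1:10, function(s) {
    g <- generate_drift_trace(drift_params(ms_rate = 1), start = c(10, 10),
                              seed = s)
    ev <- detect_microsaccades(g$trace)
    nrow(g$labels) == 1 && nrow(ev) >= 1 &&
      any(ev$start_ms - 40 <= g$labels$t_ms[1] &
          ev$end_ms + 40 >= g$labels$t_ms[1])
  }, logical(1))
  expect_true(all(hits))
})

test_that("sessions mirror the 5 x 20 trial protocol and couple acuity to density", {
  ses <- generate_session(mosaic_params(field_arcmin = c(18, 18)), seed = 2)
  expect_equal(nrow(ses$trials), 100)
  expect_equal(as.integer(table(ses$trials$run)), rep(20L, 5))
  expect_length(ses$traces, 100)
  expect_true(all(ses$trials$correct ==
                  (ses$trials$orientation == ses$trials$response)))
  # observer tied to the eye's Nyquist limit
  expect_equal(ses$truth$observer_alpha,
               0.84 * ses$landmarks$nyquist_arcsec, tolerance = 1e-9)
  # end-to-end: fitted threshold close to the generating observer
  fit <- fit_psychometric(ses$trials, n_boot = 0)
  expect_lt(abs(fit$threshold_arcsec - ses$truth$observer_alpha), 3)

  # denser mosaic -> lower recovered threshold under the same acuity rule
  thr <- vapply(c(11000, 16000), function(rho) {
    s <- generate_session(mosaic_params(center_density = rho,
                                        field_arcmin = c(18, 18)), seed = 9)
    fit_psychometric(s$trials, n_boot = 0)$threshold_arcsec
  }, numeric(1))
  expect_gt(thr[1], thr[2])
})

test_that("CDC-directed drift contracts the stimulus offset scatter", {
  set.seed(20)
  cdc <- c(12, 12)
  pts <- t(vapply(1:150, function(i) {
    start <- c(rnorm(1, 14, 2.5), rnorm(1, 13, 2.5))
    g <- generate_drift_trace(drift_params(kappa = 4), start = start,
                              target = cdc)
    idx <- which(g$trace$t_ms >= 300 & g$trace$t_ms <= 800)
    c(g$trace$x[idx[1]], g$trace$y[idx[1]],
      g$trace$x[max(idx)], g$trace$y[max(idx)])
  }, numeric(4)))
  expect_lt(isoa(pts[, 3:4])$area, isoa(pts[, 1:2])$area)
})
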