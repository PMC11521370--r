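test_that("gaze traces validate their time base and window", {
  expect_error(gaze_trace(c(0, 100, 100), 1:3, 1:3), "increasing")
  expect_error(gaze_trace(c(0, 100, 200), 1:3, 1:3, window = c(0, 500)),
               "within the trace")
  expect_error(gaze_trace(c(0, 600), 1:2, 1:2, window = c(500, 100)),
               "onset")
})

test_that("drift length is the concatenated frame-wise path, not the net offset", {
  # straight line: 15 samples, 0.5 arcmin steps -> 7 arcmin, 14 arcmin/s
  tr <- gaze_trace(seq(0, 500, length.out = 15),
                   seq(0, by = 0.5, length.out = 15), rep(2, 15))
  dl <- drift_length(tr)
  expect_equal(dl$length, 7)
  expect_equal(dl$velocity, 14)
  # a closed loop keeps its full path length
  th <- seq(0, 2 * pi, length.out = 16)
  loop <- gaze_trace(seq(0, 500, length.out = 16),
                     3 + cos(th), 3 + sin(th))
  expect_equal(drift_length(loop)$length,
               sum(sqrt(diff(cos(th))^2 + diff(sin(th))^2)))
  expect_gt(drift_length(loop)$length, 6)
  # triangle inequality against the net displacement
  set.seed(1)
  for (i in 1:10) {
    x <- cumsum(rnorm(16, 0, 0.3)); y <- cumsum(rnorm(16, 0, 0.3))
    g <- gaze_trace(seq(0, 500, length.out = 16), x, y)
    expect_gte(drift_length(g)$length,
               sqrt((x[16] - x[1])^2 + (y[16] - y[1])^2) - 1e-12)
  }
  expect_error(drift_length(gaze_trace(c(0, 400, 600), 1:3, 1:3,
                                       window = c(350, 450))),
               "fewer than 2")
})

test_that("drift directions follow the screen-up-positive convention", {
  mk <- function(dx, dy) gaze_trace(c(0, 500), c(1, 1 + dx), c(2, 2 + dy))
  expect_equal(drift_direction(mk(1, 0)), 0)
  expect_equal(drift_direction(mk(0, -1)), 90)   # screen up
  expect_equal(drift_direction(mk(-1, 0)), 180)
  expect_equal(drift_direction(mk(0, 1)), -90)
  expect_true(is.na(drift_direction(mk(0, 0))))
})

test_that("landmark-relative angles are signed CCW with 0 = toward", {
  onset <- c(2, 2); lmk <- c(4, 2)   # landmark to the right
  mk <- function(dx, dy) gaze_trace(c(0, 500), c(2, 2 + dx), c(2, 2 + dy))
  expect_equal(angle_to_landmark(mk(1, 0), lmk), 0)
  expect_equal(angle_to_landmark(mk(-1, 0), lmk), 180)
  expect_equal(angle_to_landmark(mk(0, -1), lmk), 90)   # CCW of toward
  expect_equal(angle_to_landmark(mk(0, 1), lmk), -90)
  expect_true(is.na(angle_to_landmark(mk(0, 0), lmk)))
  expect_true(is.na(angle_to_landmark(mk(1, 0), c(2, 2))))
  # rotation invariance: rotating trace and landmark together changes nothing
  set.seed(2)
  for (i in 1:15) {
    x <- c(0, cumsum(rnorm(9, 0.1, 0.3))); y <- c(0, cumsum(rnorm(9, 0, 0.3)))
    lm0 <- c(3, 1)
    th0 <- angle_to_landmark(gaze_trace(seq(0, 500, length.out = 10), x, y), lm0)
    a <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    xy <- cbind(x, y) %*% t(R)
    lmr <- as.numeric(R %*% lm0)
    thr <- angle_to_landmark(gaze_trace(seq(0, 500, length.out = 10),
                                        xy[, 1], xy[, 2]), lmr)
    expect_equal(thr, th0, tolerance = 1e-9)
  }
})

test_that("tuning ratio and quadrant frequencies follow their definition", {
  # 49 / 17 / 17 / 17 split -> ratio 2.88
  ang <- c(rep(0, 49), rep(90, 17), rep(180, 17), rep(-90, 17))
  f <- quadrant_frequencies(ang)
  expect_equal(sum(f), 1)
  expect_equal(unname(f["toward"]), 0.49)
  expect_equal(tuning_ratio(ang), 0.49 / 0.17, tolerance = 1e-12)
  # half-open bin edges: +45 falls CCW, -45 falls toward
  expect_equal(unname(quadrant_frequencies(c(45))["ccw"]), 1)
  expect_equal(unname(quadrant_frequencies(c(-45))["toward"]), 1)
  expect_equal(unname(quadrant_frequencies(c(180))["away"]), 1)
  # all angles toward: infinite ratio with a warning
  expect_warning(r <- tuning_ratio(rep(0, 20)), "infinite")
  expect_identical(r, Inf)
  expect_error(tuning_ratio(NA_real_), "no defined")
})

test_that("the Rayleigh test matches its closed-form approximation", {
  r <- rayleigh_test(rep(33, 50))
  expect_equal(r$r_bar, 1)
  expect_lt(r$p, 1e-10)
  expect_error(rayleigh_test(c(1, 2, 3, 4)), "at least 5")
  # strong von Mises concentration is detected essentially always
  set.seed(4)
  rej <- vapply(1:200, function(i) {
    a <- rvonmises(100, 0.3, 1) * 180 / pi
    rayleigh_test(a)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})

test_that("ISOA scales with the point cloud and rejects degenerate input", {
  set.seed(5)
  pts <- cbind(rnorm(500, 0, 1.5), rnorm(500, 0, 1.5))
  a1 <- isoa(pts)$area
  a2 <- isoa(pts * 2)$area
  expect_equal(a2 / a1, 4, tolerance = 0.03)
  expect_error(isoa(cbind(rep(1, 20), rep(2, 20))), "identical")
  expect_error(isoa(cbind(1:5, 1:5)), "at least 10")
  # the contour level really encloses the stated mass of the KDE
  res <- isoa(pts)
  expect_gt(res$area, 0)
  expect_gte(length(res$contours), 1)
  expect_true(all(vapply(res$contours, function(cl) cl$level == res$level,
                         logical(1))))
})

test_that("microsaccade detection separates ballistic events from drift", {
  # constant slow drift at ~20 arcmin/s: no events
  t <- seq(0, 1000, by = 1000 / 30)
  slow <- gaze_trace(t, 5 + 0.02 * t, rep(5, length(t)),   # 20 arcmin/s
                     window = c(300, 800))
  expect_equal(nrow(detect_microsaccades(slow)), 0)
  expect_false(as.logical(trial_excluded(slow)))
  # one injected 30-arcmin single-frame excursion inside the window
  set.seed(6)
  x <- 5 + cumsum(c(0, rnorm(length(t) - 1, 0, 0.2)))
  y <- 5 + cumsum(c(0, rnorm(length(t) - 1, 0, 0.2)))
  mid <- which.min(abs(t - 500))
  x[mid:length(t)] <- x[mid:length(t)] + 30
  jump <- gaze_trace(t, x, y, window = c(300, 800))
  ev <- detect_microsaccades(jump)
  expect_equal(nrow(ev), 1)
  expect_true(ev$start_ms <= t[mid] && ev$end_ms >= t[mid - 1])
  expect_gt(ev$peak_velocity, 120)
  excl <- trial_excluded(jump)
  expect_true(as.logical(excl))
  expect_equal(attr(excl, "reason"), "microsaccade")
  # a long sample gap inside the window marks a blink exclusion
  keep <- t < 400 | t > 520
  gap <- gaze_trace(t[keep], (5 + 0.001 * t)[keep], rep(5, sum(keep)),
                    window = c(300, 800))
  exg <- trial_excluded(gap)
  expect_true(as.logical(exg))
  expect_equal(attr(exg, "reason"), "gap")
  expect_error(detect_microsaccades(gaze_trace(c(0, 50), 1:2, 1:2,
                                               window = c(0, 50))),
               "100 ms")
})

test_that("convergence ratio compares onset and offset landmark distances", {
  mk <- function(x1, x2) gaze_trace(c(0, 500), c(x1, x2), c(0, 0))
  lmk <- c(0, 0)
  expect_equal(convergence_ratio(mk(10, 5), lmk), 0.5)
  expect_equal(convergence_ratio(mk(10, 10), lmk), 0)
  expect_equal(convergence_ratio(mk(10, 12), lmk), -0.2)
  expect_true(is.na(convergence_ratio(mk(0, 3), lmk)))
})

test_that("sampling gain relates trial maximum and CDC potential to the onset", {
  expect_equal(sampling_gain(fake_series(rep(12000, 10))), 1)
  expect_equal(sampling_gain(fake_series(seq(10000, 11000, length.out = 15))),
               1.10)
  s <- fake_series(c(10000, 10500, 10200))
  expect_equal(potential_sampling_gain(s, 13000), 1.3)
  expect_gt(potential_sampling_gain(s, 13000), sampling_gain(s))
})

test_that("directionality aggregates rank the biased landmark first", {
  gm <- list(cdc = c(12, 12), prl = c(17, 13), pcd = c(12.3, 11.8))
  lm <- structure(list(pcd = list(location = c(x = gm$pcd[1], y = gm$pcd[2]),
                                  value = 14000, degenerate_tie = FALSE),
                       cdc = c(x = gm$cdc[1], y = gm$cdc[2]),
                       prl = c(x = gm$prl[1], y = gm$prl[2]),
                       cdc_density = 14000, icd_arcmin = 0.54,
                       nyquist_arcmin = 0.47, nyquist_arcsec = 28.1),
                  class = "foveolar_landmarks")
  set.seed(8)
  rows <- lapply(1:300, function(i) {
    start <- c(runif(1, 6, 18), runif(1, 6, 18))
    g <- generate_drift_trace(drift_params(kappa = 2), start = start,
                              target = gm$cdc, trial = i)
    drift_metrics(g$trace, lm)
  })
  met <- do.call(rbind, rows)
  agg <- aggregate_directionality(met)
  expect_equal(sum(agg$cdc$frequencies), 1)
  expect_gt(agg$cdc$tuning_ratio, 1.5)
  expect_gt(agg$cdc$tuning_ratio, agg$prl$tuning_ratio)
  expect_lt(agg$cdc$rayleigh$p, 0.001)
  # all drifts straight at the CDC: toward-frequency 1
  straight <- do.call(rbind, lapply(1:10, function(i) {
    g <- gaze_trace(seq(0, 500, length.out = 16),
                    seq(16, 15, length.out = 16), rep(12, 16))
    drift_metrics(g, lm)
  }))
  suppressWarnings(agg2 <- aggregate_directionality(straight))
  expect_equal(unname(agg2$cdc$frequencies["toward"]), 1)
})
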