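test_that("MSD of a stationary track is identically zero", {
  tr <- data.frame(track_id = 1L, frame = 0:19, x_um = 1, y_um = 2)
  curve <- msd_curve(tr, 0.02, max_lag = 5)
  expect_true(all(curve$msd_um2 == 0))
  expect_true(all(diff(curve$lag_s) > 0))
  expect_true(all(diff(curve$n_pairs) < 0))
})

test_that("MSD of deterministic drift is exactly quadratic", {
  v <- 1.3  # um/s
  dt <- 0.02
  tr <- data.frame(track_id = 1L, frame = 0:29, x_um = v * dt * (0:29),
                   y_um = 0)
  curve <- msd_curve(tr, dt, max_lag = 6)
  expect_equal(curve$msd_um2, (v * curve$lag_s)^2, tolerance = 1e-12)
})

test_that("Brownian track ensembles give MSD slope 4*D", {
  set.seed(201)
  tr <- brownian_tracks(500, 50, d_lat = 0.15, dt = 0.02)
  curve <- msd_curve(tr, 0.02, max_lag = 4)
  slope <- coef(lm(msd_um2 ~ lag_s, curve))[[2L]]
  expect_equal(slope, 4 * 0.15, tolerance = 0.05)
})

test_that("fit_dlat is slope/4 on exact lines", {
  dt <- 0.02
  mk <- function(slope) {
    tr <- brownian_tracks(5, 30, 0.1, dt)
    curve <- msd_curve(tr, dt, max_lag = 6)
    curve$msd_um2 <- slope * curve$lag_s
    curve
  }
  # slopes chosen to match mobilities typical of cultured cells and tissue
  expect_equal(fit_dlat(mk(0.436))$d_lat, 0.109, tolerance = 1e-10)
  expect_equal(fit_dlat(mk(2.52))$d_lat, 0.63, tolerance = 1e-10)
  expect_equal(fit_dlat(mk(1))$intercept, 0, tolerance = 1e-10)
})

test_that("fit_dlat is scale-equivariant", {
  set.seed(202)
  tr <- brownian_tracks(50, 30, 0.2, 0.02)
  d1 <- fit_dlat(msd_curve(tr, 0.02, max_lag = 4))$d_lat
  tr2 <- tr
  tr2$x_um <- 3 * tr$x_um; tr2$y_um <- 3 * tr$y_um
  d2 <- fit_dlat(msd_curve(tr2, 0.02, max_lag = 4))$d_lat
  expect_equal(d2, 9 * d1, tolerance = 1e-10)
})

test_that("msd_curve pools track sets as a pair-count-weighted combination", {
  set.seed(203)
  a <- brownian_tracks(20, 25, 0.1, 0.02)
  b <- brownian_tracks(30, 25, 0.4, 0.02)
  b$track_id <- b$track_id + 100L
  ca <- msd_curve(a, 0.02, max_lag = 3)
  cb <- msd_curve(b, 0.02, max_lag = 3)
  cab <- msd_curve(rbind(a, b), 0.02, max_lag = 3)
  pooled <- (ca$msd_um2 * ca$n_pairs + cb$msd_um2 * cb$n_pairs) /
    (ca$n_pairs + cb$n_pairs)
  expect_equal(cab$msd_um2, pooled, tolerance = 1e-12)
  expect_identical(cab$n_pairs, ca$n_pairs + cb$n_pairs)
})

test_that("motion classification separates free, directed and caged motion", {
  set.seed(204)
  free <- vapply(seq_len(20), function(i) {
    tr <- brownian_tracks(60, 40, 0.15, 0.02)
    classify_motion(msd_curve(tr, 0.02, max_lag = 8))$motion_class
  }, character(1))
  expect_gte(mean(free == "free"), 0.95)
  drift <- brownian_tracks(60, 40, 0.15, 0.02, drift = c(1.5, 0))
  expect_identical(
    classify_motion(msd_curve(drift, 0.02, max_lag = 8))$motion_class,
    "flow")
  caged <- brownian_tracks(80, 60, 0.15, 0.02, confine_half = 0.1)
  expect_identical(
    classify_motion(msd_curve(caged, 0.02, max_lag = 10))$motion_class,
    "caged")
})

test_that("temperature fit recovers exact doubling per 10 C", {
  tt <- seq(-5, 45, by = 5)
  fit <- fit_temperature(tt, 0.1 * 2^((tt - 23) / 10))
  expect_equal(fit$q10, 2, tolerance = 1e-6)
  expect_equal(fit$d_ref, 0.1, tolerance = 1e-6)
  # constant D: no temperature dependence
  flat <- fit_temperature(c(10, 20, 30, 40), rep(0.2, 4))
  expect_equal(flat$q10, 1, tolerance = 1e-8)
  expect_equal(flat$k, 0, tolerance = 1e-8)
})

test_that("temperature fit recovers Q10 from noisy data within 10%", {
  set.seed(205)
  tt <- seq(-5, 45, length.out = 12)
  q10 <- numeric(30)
  for (i in seq_along(q10)) {
    d <- 0.12 * 2^((tt - 23) / 10) * exp(rnorm(12, 0, 0.1))
    q10[i] <- fit_temperature(tt, d)$q10
  }
  expect_lt(max(abs(q10 - 2) / 2), 0.15)
  expect_equal(mean(q10), 2, tolerance = 0.05)
})

test_that("temperature fit input validation", {
  expect_error(fit_temperature(c(10, 12), c(0.1, 0.12)), "3 temperature")
  expect_error(fit_temperature(c(10, 12, 14), c(0.1, 0.11, 0.12)),
               "spanning")
  expect_warning(fit_temperature(c(10, 20, 30, 40), c(0.1, 0.2, -1, 0.4)),
                 "non-positive")
  fit <- fit_temperature(seq(0, 40, 10), 0.1 * 2^((seq(0, 40, 10) - 23) / 10))
  expect_equal(predict_dlat(fit, 33), 2 * predict_dlat(fit, 23),
               tolerance = 1e-6)
})
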