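test_that("zero density gives a pure-background movie and empty truth", {
  cfg <- movie_config(field_width = 4, field_height = 4,
                      receptor_density = 0, n_frames = 3, rng_seed = 1)
  sim <- simulate_movie(cfg)
  expect_identical(nrow(sim$truth), 0L)
  expect_identical(dim(sim$movie), c(40L, 40L, 3L))
  # background only: mean near background_mean, no bright outliers
  expect_equal(mean(sim$movie), cfg$background_mean, tolerance = 0.02)
  expect_lt(max(sim$movie), cfg$background_mean + 10 * cfg$background_noise_sd)
})

test_that("config validation rejects non-physical parameters", {
  expect_error(movie_config(receptor_density = -1), "receptor_density")
  expect_error(movie_config(pixel_size = 0.1, psf_fwhm = 0.15), "psf_fwhm")
  expect_error(movie_config(immobile_fraction = 1.5), "immobile_fraction")
  expect_error(movie_config(d_lat = NaN), "d_lat")
})

test_that("ground-truth steps have per-axis variance 2*D*dt", {
  cfg <- movie_config(field_width = 90, field_height = 90,
                      receptor_density = 500 / 8100, d_lat = 0.15,
                      frame_interval = 0.02, n_frames = 100,
                      photons_per_spot = 0, background_mean = 0,
                      background_noise_sd = 0, rng_seed = 42)
  sim <- simulate_movie(cfg)
  tr <- unwrap_truth(sim$truth, cfg)
  steps <- unlist(lapply(split(tr$x_um, tr$particle_id), diff))
  expect_gt(length(steps), 4e4)
  expect_equal(var(steps), 2 * 0.15 * 0.02, tolerance = 0.05)
})

test_that("ground-truth MSD is linear with slope 4*D", {
  cfg <- movie_config(field_width = 80, field_height = 80,
                      receptor_density = 550 / 6400, d_lat = 0.2,
                      frame_interval = 0.02, n_frames = 60,
                      photons_per_spot = 0, background_mean = 0,
                      background_noise_sd = 0, rng_seed = 7)
  sim <- simulate_movie(cfg)
  tr <- unwrap_truth(sim$truth, cfg)
  tr$track_id <- tr$particle_id
  curve <- msd_curve(tr, cfg$frame_interval, max_lag = 4)
  est <- fit_dlat(curve, 4)
  expect_equal(est$d_lat, 0.2, tolerance = 0.05)
})

test_that("rendered photons per unbleached monomer match the photon budget", {
  cfg <- movie_config(field_width = 6, field_height = 6,
                      receptor_density = 0.5, d_lat = 0.1, n_frames = 400,
                      photons_per_spot = 600, rng_seed = 11)
  sim <- simulate_movie(cfg)
  n <- length(unique(sim$truth$particle_id))
  expect_gt(n, 5)
  n_px <- prod(dim(sim$movie)[1:2])
  tot <- apply(sim$movie, 3L, sum) - cfg$background_mean * n_px
  per_emitter <- tot / n
  se <- sd(per_emitter) / sqrt(length(per_emitter))
  expect_lt(abs(mean(per_emitter) - 600), 2 * se + 1)
})

test_that("emitting-spot count decays as exp(-k_bleach * t)", {
  cfg <- movie_config(field_width = 30, field_height = 30,
                      receptor_density = 1, d_lat = 0.1,
                      frame_interval = 0.05, n_frames = 80,
                      bleach_rate = 0.5, photons_per_spot = 0,
                      background_mean = 0, background_noise_sd = 0,
                      rng_seed = 13)
  sim <- simulate_movie(cfg)
  alive <- tapply(!sim$truth$bleached, sim$truth$frame, sum)
  t <- as.numeric(names(alive)) * cfg$frame_interval
  n0 <- alive[[1L]]
  expected <- n0 * exp(-0.5 * t)
  # each frame within Poisson error of the exponential decay
  resid <- (alive - expected) / sqrt(pmax(expected, 1))
  expect_lt(mean(abs(resid)), 2)
  fit <- fit_bleach_rate(t, as.numeric(alive))
  expect_equal(fit$k_bleach, 0.5, tolerance = 0.1)
})

test_that("a bleached fluorophore never re-emits and wrapping unwraps", {
  cfg <- movie_config(field_width = 5, field_height = 5,
                      receptor_density = 2, d_lat = 1, n_frames = 60,
                      bleach_rate = 1, frame_interval = 0.05,
                      photons_per_spot = 0, background_mean = 0,
                      background_noise_sd = 0, rng_seed = 17)
  sim <- simulate_movie(cfg)
  by_p <- split(sim$truth$bleached, sim$truth$particle_id)
  expect_true(all(vapply(by_p, function(b) all(diff(b) >= 0), logical(1))))
  # wrapped positions stay inside the field; unwrapped steps stay small
  expect_true(all(sim$truth$x_um >= 0 & sim$truth$x_um < 5))
  tr <- unwrap_truth(sim$truth, cfg)
  steps <- abs(unlist(lapply(split(tr$x_um, tr$particle_id), diff)))
  expect_lt(max(steps), 2.5)  # < half the box once unwrapped
})

test_that("dimer partnership is symmetric and renders coincident", {
  cfg <- movie_config(field_width = 12, field_height = 12,
                      receptor_density = 2, d_lat = 0.15, n_frames = 40,
                      dimer_on_rate = 0.2, dimer_off_rate = 1,
                      photons_per_spot = 0, background_mean = 0,
                      background_noise_sd = 0, rng_seed = 19)
  sim <- simulate_movie(cfg)
  tr <- sim$truth
  paired <- tr[!is.na(tr$partner_id), ]
  expect_gt(nrow(paired), 0)
  key <- paste(paired$frame, paired$particle_id)
  partner_key <- paste(paired$frame, paired$partner_id)
  idx <- match(partner_key, key)
  expect_false(anyNA(idx))
  expect_identical(paired$partner_id[idx], paired$particle_id)
  expect_equal(paired$x_um[idx], paired$x_um)
  expect_equal(paired$y_um[idx], paired$y_um)
})

test_that("dimer kinetics: no association without k_on, instant loss at huge k_off", {
  tl0 <- simulate_dimer_kinetics(density = 2, k_on = 0, k_off = 1,
                                 duration = 5, dt = 0.01, box_side = 8,
                                 seed = 1)
  expect_true(all(tl0$n_dimer == 0))
  tl_fast <- simulate_dimer_kinetics(density = 2, k_on = 0.1, k_off = 500,
                                     duration = 5, dt = 0.01, box_side = 8,
                                     seed = 2)
  dw <- attr(tl_fast, "dwell_times")
  # with k_off >> 1/dt every dimer dissolves within ~a single step
  expect_lt(mean(dw), 3 * 0.01)
  expect_identical(nrow(simulate_dimer_kinetics(1, 0.1, 1, 0)), 0L)
})

test_that("mean dimer dwell time is 1/k_off", {
  tl <- simulate_dimer_kinetics(density = 2, k_on = 0.3, k_off = 2,
                                duration = 40, dt = 0.005, box_side = 10,
                                seed = 5)
  dw <- attr(tl, "dwell_times")
  expect_gt(length(dw), 500)
  expect_equal(mean(dw), 1 / 2, tolerance = 0.1)
})

test_that("equilibrium dimer fraction increases with density", {
  fr <- vapply(c(1, 2, 4), function(rho) {
    tl <- simulate_dimer_kinetics(density = rho, k_on = 0.1, k_off = 1,
                                  duration = 25, dt = 0.01, box_side = 10,
                                  seed = 31)
    attr(tl, "dimer_fraction")
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})
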