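test_that("median smoothing removes spikes, keeps steps, passes monotones", {
  expect_equal(median_smooth(c(5, 5, 50, 5, 5)), rep(5, 5))
  expect_equal(median_smooth(1:8), as.numeric(1:8))
  sm <- median_smooth(c(0, 0, 0, 10, 10, 10))
  expect_equal(sm, c(0, 0, 0, 10, 10, 10))  # genuine step preserved
  expect_error(median_smooth(c(1, 2)), "length")
})

test_that("median smoothing is idempotent once spikes are gone", {
  x <- rep(c(2, 1, 0), each = 15)
  x[c(7, 22, 38)] <- x[c(7, 22, 38)] + 30  # isolated spikes
  y <- median_smooth(x)
  expect_equal(y, rep(c(2, 1, 0), each = 15))  # spikes removed
  expect_equal(median_smooth(y), y)            # and nothing else changes
  # on arbitrary noise, iterating reaches a fixed point (a filter root)
  set.seed(301)
  z <- rnorm(50)
  for (i in 1:25) z <- median_smooth(z)
  expect_equal(median_smooth(z), z)
})

test_that("noiseless steps are found at the exact frame", {
  fit <- detect_steps(c(5, 5, 5, 0, 0, 0))
  expect_identical(fit$transitions, 3L)
  expect_equal(fit$levels, c(5, 0))
  fit2 <- detect_steps(rep(c(10, 5, 0), each = 10))
  expect_identical(fit2$transitions, c(10L, 20L))
  expect_equal(fit2$levels, c(10, 5, 0))
  # shorter than the derivative window: single-level fit
  short <- detect_steps(c(3, 3, 3))
  expect_identical(short$transitions, integer(0))
  expect_equal(short$levels, 3)
})

test_that("two-step staircases at 20% noise are recovered within 2 frames", {
  set.seed(302)
  hits <- vapply(seq_len(400), function(i) {
    tr <- detect_steps(median_smooth(
      staircase_trace(c(2, 1, 0), 20, 0.2)))$transitions
    length(tr) == 2L && abs(tr[1L] - 20L) <= 2L && abs(tr[2L] - 40L) <= 2L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("constant noisy traces produce no transitions at 4 SD", {
  set.seed(303)
  clean <- vapply(seq_len(400), function(i)
    length(detect_steps(rnorm(60))$transitions) == 0L, logical(1))
  expect_gte(mean(clean), 0.99)
})

test_that("step detection is invariant to a constant offset", {
  set.seed(304)
  for (i in 1:20) {
    x <- staircase_trace(c(3, 1.5, 0), 15, 0.15)
    expect_identical(detect_steps(x)$transitions,
                     detect_steps(x + 250)$transitions)
  }
})

test_that("trajectory classification follows the type taxonomy", {
  mk <- function(levels) {
    structure(list(transitions = seq_along(levels)[-length(levels)] * 10L,
                   levels = levels,
                   level_start = c(1L, seq_along(levels)[-length(levels)] *
                                     10L + 1L),
                   noise_sd = 0.05), class = "step_fit")
  }
  u <- 1
  expect_identical(classify_trajectory(mk(c(1, 0)), u), "type1")
  expect_identical(classify_trajectory(mk(c(2, 1, 0)), u), "type2")
  expect_identical(classify_trajectory(mk(c(1, 2, 0)), u), "type3")
  expect_identical(classify_trajectory(mk(c(1, 2, 1, 0)), u), "dimer_other")
  expect_identical(classify_trajectory(mk(c(2, 0)), u), "dimer_other")
  expect_identical(classify_trajectory(mk(c(3, 2, 1, 0)), u),
                   "higher_oligomer")
  # censored (never returns to background) and off-grid levels
  expect_identical(classify_trajectory(mk(c(1, 2)), u), "unclassified")
  expect_identical(classify_trajectory(mk(c(1.55, 0)), u), "unclassified")
  # tolerance: within 35% of the unit grid still classifies
  expect_identical(classify_trajectory(mk(c(1.3, 0)), u), "type1")
  expect_error(classify_trajectory(mk(c(1, 0)), 0), "unit_intensity")
})

test_that("intensity traces report the rendered photon budget per pixel", {
  cfg <- movie_config(field_width = 5, field_height = 5,
                      receptor_density = 0, n_frames = 120, rng_seed = 305)
  sim <- simulate_movie(cfg)
  # inject one immobile emitter by rendering a second movie with a single
  # particle: use a tiny density and keep only runs with exactly 1 particle
  cfg1 <- movie_config(field_width = 5, field_height = 5,
                       receptor_density = 0.25, d_lat = 0, n_frames = 120,
                       immobile_fraction = 1, rng_seed = 306)
  sim1 <- simulate_movie(cfg1)
  n <- length(unique(sim1$truth$particle_id))
  expect_gt(n, 0)
  spots <- detect_spots(sim1$movie, frame = 0)
  tr <- data.frame(track_id = 1L, frame = 0:119,
                   x_um = spots$x_um[1L], y_um = spots$y_um[1L],
                   intensity = NA, background = NA)
  trace <- extract_intensity_trace(sim1$movie, tr)
  # expected counts/pixel: photon budget times the analytic capture
  # fraction of a 5x5 window at the spot position, over 25 pixels
  sigma <- fwhm_to_sigma(0.3)
  px <- 0.1
  u <- spots$x_um[1L] / px; v <- spots$y_um[1L] / px
  capt <- function(c0) diff(pnorm(c(round(c0) - 2.5, round(c0) + 2.5),
                                  c0, sigma / px))
  expected <- 600 * capt(u) * capt(v) / 25
  got <- mean(trace$intensity)
  se <- sd(trace$intensity) / sqrt(nrow(trace))
  expect_lt(abs(got - expected), 3 * se + 0.5)
})

test_that("a dimer trace is twice the monomer trace", {
  # two coincident emitters rendered at a fixed spot vs one
  set.seed(307)
  mono <- replicate(150, {
    img <- render_test_frame(2, 2, photons = 600)
    mean(img[18:22, 18:22]) - median(img)
  })
  dim2 <- replicate(150, {
    img <- render_test_frame(c(2, 2), c(2, 2), photons = 600)
    mean(img[18:22, 18:22]) - median(img)
  })
  expect_equal(mean(dim2) / mean(mono), 2, tolerance = 0.05)
})

test_that("intensity histogram calibrates the monomer mode and dimer tail", {
  set.seed(308)
  mono <- rnorm(800, 600, 72)
  expect_lte(intensity_histogram(mono)$tail_fraction, 0.05)
  mix <- c(rnorm(800, 600, 72), rnorm(200, 1200, 144))
  h <- intensity_histogram(mix)
  expect_equal(h$mode, 600, tolerance = 0.1)
  expect_equal(h$tail_fraction, 0.2, tolerance = 0.25)
  expect_identical(intensity_histogram(rep(5, 200))$tail_fraction, 0)
  expect_error(intensity_histogram(rnorm(50)), "100")
})

test_that("chance coincidence is rare when sustained overlap is required", {
  # at the density where ~10% of tracks show ~1 s doubled-intensity
  # episodes, chance overlap sustained for 1 s explains almost none of them
  cn <- coincidence_null(density = 1.5, d_lat = 0.15,
                         coincidence_dist = 0.3, duration = 1,
                         frame_interval = 0.02, min_overlap_s = 1,
                         box_side = 12, seed = 309)
  expect_lt(cn$fraction, 0.10)
  # no particles, no coincidences
  expect_identical(coincidence_null(0, 0.15, seed = 1)$fraction, 0)
})

test_that("instantaneous chance coincidence grows with density", {
  fr <- vapply(c(0.5, 1, 2), function(rho)
    coincidence_null(rho, 0.15, 0.3, duration = 1, frame_interval = 0.02,
                     min_overlap_s = 0.02, box_side = 10,
                     seed = 310)$fraction,
    numeric(1))
  expect_true(all(diff(fr) > 0))
})
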