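test_that("blank noise frames yield essentially no false detections at 5 SD", {
  set.seed(101)
  hits <- vapply(seq_len(400), function(i) {
    img <- render_test_frame(numeric(0), numeric(0), nx = 64, ny = 64)
    nrow(detect_spots(img, 0.1))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.99)
})

test_that("single-spot localization achieves 25 nm RMS precision", {
  set.seed(102)
  errs <- vapply(seq_len(300), function(i) {
    x0 <- 2 + runif(1, -0.05, 0.05)
    y0 <- 2 + runif(1, -0.05, 0.05)
    sp <- detect_spots(render_test_frame(x0, y0), 0.1)
    if (nrow(sp) != 1L) return(NA_real_)
    (sp$x_um - x0)^2 + (sp$y_um - y0)^2
  }, numeric(1))
  expect_lt(mean(is.na(errs)), 0.02)
  expect_lte(sqrt(mean(errs, na.rm = TRUE)), 0.025)
})

test_that("well-separated spots are each detected once", {
  set.seed(103)
  img <- render_test_frame(c(1.5, 2.5), c(2, 2))
  sp <- detect_spots(img, 0.1)
  expect_identical(nrow(sp), 2L)
  expect_equal(sort(sp$x_um), c(1.5, 2.5), tolerance = 0.05)
  # integrated intensity is background-subtracted counts over the window
  expect_equal(mean(sp$intensity), 600 * 0.90, tolerance = 0.15)
})

test_that("detection count matches ground truth at sparse density", {
  # the whole field is usable (periodic padding); the only systematic loss
  # left at 0.2 um^-2 is the few-percent merging of sub-resolution pairs
  cfg <- movie_config(field_width = 10, field_height = 10,
                      receptor_density = 0.2, d_lat = 0.15,
                      frame_interval = 0.02, n_frames = 100, rng_seed = 104)
  sim <- simulate_movie(cfg)
  n_true <- length(unique(sim$truth$particle_id))
  per_frame <- as.vector(table(factor(detect_movie(sim$movie)$frame,
                                      levels = 0:99)))
  expect_lt(abs(mean(per_frame) / n_true - 1), 0.05)
})

test_that("FWHM measurement recovers the diffraction-limited width", {
  set.seed(105)
  fw <- vapply(seq_len(40), function(i) {
    img <- render_test_frame(2 + runif(1, -0.05, 0.05), 2, photons = 2000)
    measure_fwhm(img, 0.1)$fwhm_um
  }, numeric(1))
  expect_equal(mean(fw), 0.30, tolerance = 0.02 / 0.30)
  # exact conversion: sigma 0.1274 um <-> FWHM 0.30 um
  expect_equal(sigma_to_fwhm(0.1274), 0.30, tolerance = 1e-3)
  expect_equal(fwhm_to_sigma(0.30), 0.1274, tolerance = 1e-3)
})

test_that("a delta-like single bright pixel is flagged sub-resolution", {
  set.seed(106)
  img <- matrix(100L, 21, 21)
  img[11, 11] <- 5000L
  res <- measure_fwhm(img, 0.1)
  expect_true(is.na(res$fwhm_um) || res$sub_resolution)
})

test_that("one persistent spot links into a single full-length track", {
  set.seed(107)
  spots <- do.call(rbind, lapply(0:49, function(f) {
    sp <- detect_spots(render_test_frame(2, 2), 0.1, frame = f)
    sp
  }))
  tracks <- link_tracks(spots, link_params(), frame_interval = 0.02)
  expect_identical(length(unique(tracks$track_id)), 1L)
  expect_identical(nrow(tracks), 50L)
  expect_true(all(diff(tracks$frame) == 1))
})

test_that("linking matches ground-truth identities at sparse density", {
  cfg <- movie_config(field_width = 20, field_height = 20,
                      receptor_density = 0.5, d_lat = 0.15,
                      frame_interval = 0.02, n_frames = 40, rng_seed = 108)
  sim <- simulate_movie(cfg)
  spots <- detect_movie(sim$movie)
  tracks <- link_tracks(spots, link_params(min_length = 5),
                        frame_interval = cfg$frame_interval)
  # match each tracked spot to the nearest ground-truth particle
  truth_id <- vapply(seq_len(nrow(tracks)), function(r) {
    tt <- sim$truth[sim$truth$frame == tracks$frame[r], ]
    d2 <- (tt$x_um - tracks$x_um[r])^2 + (tt$y_um - tracks$y_um[r])^2
    tt$particle_id[which.min(d2)]
  }, numeric(1))
  same <- unlist(lapply(split(truth_id, tracks$track_id), function(ids)
    ids[-1L] == ids[-length(ids)]))
  expect_gte(mean(same), 0.90)
})

test_that("no two spots in one frame join the same track", {
  cfg <- movie_config(field_width = 15, field_height = 15,
                      receptor_density = 1, d_lat = 0.3,
                      frame_interval = 0.02, n_frames = 25, rng_seed = 109)
  sim <- simulate_movie(cfg)
  tracks <- link_tracks(detect_movie(sim$movie), link_params(),
                        frame_interval = 0.02)
  dup <- any(vapply(split(tracks$frame, tracks$track_id),
                    anyDuplicated, integer(1)) > 0)
  expect_false(dup)
})

test_that("a mid-movie bleach terminates the track at the bleach frame", {
  set.seed(110)
  bleach_frame <- 23L
  spots <- do.call(rbind, lapply(0:49, function(f) {
    if (f > bleach_frame) {
      img <- render_test_frame(numeric(0), numeric(0))
    } else {
      img <- render_test_frame(2, 2)
    }
    detect_spots(img, 0.1, frame = f)
  }))
  tracks <- link_tracks(spots, link_params(), frame_interval = 0.02)
  expect_identical(length(unique(tracks$track_id)), 1L)
  expect_lte(abs(max(tracks$frame) - bleach_frame), 1L)
})

test_that("immobile spots produce tracks with near-zero MSD slope", {
  set.seed(111)
  spots <- do.call(rbind, lapply(0:29, function(f)
    detect_spots(render_test_frame(c(1.2, 2.8), c(1.2, 2.8)), 0.1,
                 frame = f)))
  tracks <- link_tracks(spots, link_params(), frame_interval = 0.02)
  # a negative raw slope is legitimately clamped to zero here
  est <- suppressWarnings(fit_dlat(msd_curve(tracks, 0.02, max_lag = 4)))
  expect_lt(est$d_lat, 0.005)
})

test_that("linking needs a displacement scale and handles empty input", {
  expect_identical(nrow(link_tracks(data.frame())), 0L)
  sp <- data.frame(frame = 0L, x_um = 1, y_um = 1, intensity = 1,
                   background = 0)
  expect_error(link_tracks(sp), "frame_interval")
})
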