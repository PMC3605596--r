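# Fixture builders shared across the suite. The frame renderer here is
# written independently of the package internals (plain integrated-Gaussian
# arithmetic) so it can serve as an oracle for the detection code.

# Render one camera frame with spots at the given positions (um).
# Coordinate convention matches the package: pixel j (0-based) is centered
# at x = j * pixel_size.
render_test_frame <- function(x_um, y_um, photons = 600, nx = 40, ny = 40,
                              pixel_size = 0.1, fwhm = 0.3, bg_mean = 100,
                              bg_sd = 6, poisson = TRUE) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  lambda <- matrix(0, ny, nx)
  if (length(x_um)) {
    if (length(photons) == 1L) photons <- rep(photons, length(x_um))
    edges_x <- (0:nx - 0.5) * pixel_size
    edges_y <- (0:ny - 0.5) * pixel_size
    for (k in seq_along(x_um)) {
      fx <- diff(pnorm(edges_x, mean = x_um[k], sd = sigma))
      fy <- diff(pnorm(edges_y, mean = y_um[k], sd = sigma))
      lambda <- lambda + photons[k] * outer(fy, fx)
    }
  }
  signal <- if (poisson) matrix(rpois(nx * ny, lambda), ny, nx) else lambda
  counts <- round(signal + matrix(rnorm(nx * ny, bg_mean, bg_sd), ny, nx))
  counts[counts < 0] <- 0
  matrix(as.integer(counts), ny, nx)
}

# Pure random-walk track table (no imaging), optionally with localization
# noise, drift, or reflective confinement in a box of the given half-side.
brownian_tracks <- function(n_tracks, n_frames, d_lat, dt,
                            sigma_loc = 0, drift = c(0, 0),
                            confine_half = NULL) {
  s <- sqrt(2 * d_lat * dt)
  out <- lapply(seq_len(n_tracks), function(id) {
    dx <- rnorm(n_frames - 1L, drift[1L] * dt, s)
    dy <- rnorm(n_frames - 1L, drift[2L] * dt, s)
    x <- cumsum(c(0, dx))
    y <- cumsum(c(0, dy))
    if (!is.null(confine_half)) {
      reflect <- function(v, h) {
        v <- (v + h) %% (4 * h)
        ifelse(v > 2 * h, 4 * h - v, v) - h
      }
      x <- reflect(x, confine_half)
      y <- reflect(y, confine_half)
    }
    data.frame(track_id = id, frame = 0:(n_frames - 1L),
               x_um = x + rnorm(n_frames, 0, sigma_loc),
               y_um = y + rnorm(n_frames, 0, sigma_loc))
  })
  do.call(rbind, out)
}

# Noisy staircase intensity trace with the given level means and equal
# segment lengths.
staircase_trace <- function(levels, seg_len, noise_sd) {
  x <- rep(levels, each = seg_len)
  x + rnorm(length(x), 0, noise_sd)
}
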