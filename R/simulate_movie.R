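# One step of the reversible monomer-dimer update shared by the movie
# simulator and the non-rendered kinetics simulator. Positions are in um in
# a periodic box of side (W, H). `partner` holds the partner index (NA for
# monomers); `eligible` marks particles that take part in dimerization.
# Association is contact driven: a monomer pair within `capture` um
# associates during dt with probability k_on * dt / (pi * capture^2), the
# discrete-time equivalent of 2-d mass action with rate constant k_on
# (um^2/s). Dissociation is first order at k_off.
step_dimer_kinetics <- function(x, y, partner, eligible, k_on, k_off, dt,
                                capture, W, H) {
  events <- list(assoc = integer(0), dissoc = integer(0))
  n <- length(x)
  if (n == 0L) return(list(partner = partner, x = x, y = y, events = events))
  # first-order dissociation
  lead <- which(!is.na(partner) & seq_len(n) < partner)
  if (length(lead) && k_off > 0) {
    p_off <- 1 - exp(-k_off * dt)
    gone <- lead[runif(length(lead)) < p_off]
    if (length(gone)) {
      events$dissoc <- gone
      partner[partner[gone]] <- NA_integer_
      partner[gone] <- NA_integer_
    }
  }
  # contact-driven association among eligible monomers
  if (k_on > 0) {
    mono <- which(is.na(partner) & eligible)
    if (length(mono) >= 2L) {
      dx <- min_image(outer(x[mono], x[mono], "-"), W)
      dy <- min_image(outer(y[mono], y[mono], "-"), H)
      close <- which(dx * dx + dy * dy < capture^2, arr.ind = TRUE)
      close <- close[close[, 1L] < close[, 2L], , drop = FALSE]
      if (nrow(close)) {
        p_on <- min(1, k_on * dt / (pi * capture^2))
        hit <- close[runif(nrow(close)) < p_on, , drop = FALSE]
        if (nrow(hit)) {
          ord <- sample.int(nrow(hit))  # random conflict resolution
          taken <- logical(length(mono))
          for (r in ord) {
            a <- hit[r, 1L]; b <- hit[r, 2L]
            if (taken[a] || taken[b]) next
            taken[a] <- taken[b] <- TRUE
            ia <- mono[a]; ib <- mono[b]
            partner[ia] <- ib; partner[ib] <- ia
            # render dimers as coincident point sources: meet at midpoint
            mx <- x[ia] + min_image(x[ib] - x[ia], W) / 2
            my <- y[ia] + min_image(y[ib] - y[ia], H) / 2
            x[ia] <- x[ib] <- mx %% W
            y[ia] <- y[ib] <- my %% H
            events$assoc <- c(events$assoc, ia)
          }
        }
      }
    }
  }
  list(partner = partner, x = x, y = y, events = events)
}

# Brownian step for all particles; dimers move jointly (one displacement per
# pair), immobile particles stay put. Returns wrapped positions and the
# number of box lengths crossed this step.
step_diffusion <- function(x, y, partner, mobile, d_lat, dt, W, H) {
  n <- length(x)
  s <- sqrt(2 * d_lat * dt)
  dx <- rnorm(n, 0, s)
  dy <- rnorm(n, 0, s)
  dx[!mobile] <- 0
  dy[!mobile] <- 0
  paired <- !is.na(partner)
  if (any(paired)) {  # the lower-indexed member's draw moves the pair
    lead <- which(paired & seq_len(n) < partner)
    dx[partner[lead]] <- dx[lead]
    dy[partner[lead]] <- dy[lead]
  }
  wx <- wrap_periodic(x + dx, W)
  wy <- wrap_periodic(y + dy, H)
  list(x = wx$x, y = wy$x, wrap_x = wx$n_wrap, wrap_y = wy$n_wrap)
}

# Render one frame: expected photon image from the emitters plus Poisson
# shot noise on the signal and Gaussian read noise on the background.
render_frame <- function(ex, ey, photons, nx, ny, pixel_size, sigma_um,
                         background_mean, background_noise_sd) {
  lambda <- matrix(0, ny, nx)
  if (length(ex)) {
    s_px <- sigma_um / pixel_size
    r <- ceiling(4 * s_px)
    for (i in seq_along(ex)) {
      u <- ex[i] / pixel_size   # pixel j is centered at coordinate u = j
      v <- ey[i] / pixel_size
      js <- (round(u) - r):(round(u) + r)
      is <- (round(v) - r):(round(v) + r)
      fx <- pnorm((js + 0.5 - u) / s_px) - pnorm((js - 0.5 - u) / s_px)
      fy <- pnorm((is + 0.5 - v) / s_px) - pnorm((is - 0.5 - v) / s_px)
      jj <- (js %% nx) + 1L
      ii <- (is %% ny) + 1L
      lambda[ii, jj] <- lambda[ii, jj] + photons[i] * outer(fy, fx)
    }
  }
  n_px <- nx * ny
  signal <- rpois(n_px, lambda)
  bg <- rnorm(n_px, background_mean, background_noise_sd)
  counts <- round(signal + bg)
  counts[counts < 0] <- 0
  counts[counts > 65535] <- 65535
  matrix(as.integer(counts), ny, nx)
}

#' Simulate a single-molecule TIRF movie with ground truth
#'
#' Generates a calibrated image stack of diffusing, photobleaching,
#' reversibly dimerizing membrane receptors together with the full
#' per-particle state history. Particles are placed uniformly at the
#' configured surface density (Poisson-distributed count); mobile particles
#' take Gaussian steps with per-axis variance `2 * d_lat * frame_interval`
#' between frames, with periodic boundary conditions; each fluorophore
#' bleaches after an exponential waiting time with rate `bleach_rate` and
#' never re-emits. Each unbleached fluorophore contributes an integrated
#' 2-d Gaussian point spread function (sigma = FWHM / 2.3548) centered at
#' its continuous position; dimers are rendered as two coincident point
#' sources, i.e. one diffraction-limited spot of double intensity until one
#' partner bleaches. Shot noise on the signal is Poisson, the background
#' carries Gaussian read noise. When dimer kinetics are enabled the
#' monomer-dimer equilibrium is pre-equilibrated before the first frame so
#' that illumination starts from the stationary mixture.
#'
#' @param config a [movie_config()].
#' @return list of class `"tirf_sim"` with elements `movie` (a
#'   [movie_stack()]), `truth` (data.frame: `particle_id`, `frame`, `x_um`,
#'   `y_um`, `bleached`, `partner_id`, `mobile`, `wrap_x`, `wrap_y`) and
#'   `config`.
#' @examples
#' sim <- simulate_movie(movie_config(field_width = 6, field_height = 6,
#'                                    receptor_density = 0.3, n_frames = 5))
#' dim(sim$movie)
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "movie_config"))
  set.seed(config$rng_seed)
  W <- config$field_width; H <- config$field_height
  dt <- config$frame_interval
  nf <- config$n_frames
  nx <- round(W / config$pixel_size)
  ny <- round(H / config$pixel_size)
  sigma_um <- fwhm_to_sigma(config$psf_fwhm)

  n <- rpois(1L, config$receptor_density * W * H)
  if (n == 0L) {
    frames <- array(0L, dim = c(ny, nx, nf))
    for (f in seq_len(nf))
      frames[, , f] <- render_frame(numeric(0), numeric(0), numeric(0),
                                    nx, ny, config$pixel_size, sigma_um,
                                    config$background_mean,
                                    config$background_noise_sd)
    truth <- data.frame(particle_id = integer(0), frame = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        bleached = logical(0), partner_id = integer(0),
                        mobile = logical(0), wrap_x = integer(0),
                        wrap_y = integer(0))
    return(structure(list(
      movie = movie_stack(frames, config$pixel_size, dt),
      truth = truth, config = config), class = "tirf_sim"))
  }

  x <- runif(n, 0, W); y <- runif(n, 0, H)
  mobile <- runif(n) >= config$immobile_fraction
  t_bleach <- if (config$bleach_rate > 0) rexp(n, config$bleach_rate)
              else rep(Inf, n)
  partner <- rep(NA_integer_, n)
  cum_wx <- integer(n); cum_wy <- integer(n)

  # burn in the monomer-dimer equilibrium before illumination starts
  if (config$dimer_on_rate > 0 && config$dimer_off_rate > 0) {
    n_burn <- ceiling(3 / (config$dimer_off_rate * dt))
    for (b in seq_len(n_burn)) {
      mv <- step_diffusion(x, y, partner, mobile, config$d_lat, dt, W, H)
      x <- mv$x; y <- mv$y
      # eligibility: mobile receptors only (immobile spots are nonspecific)
      st <- step_dimer_kinetics(x, y, partner, mobile,
                                config$dimer_on_rate, config$dimer_off_rate,
                                dt, config$capture_dist, W, H)
      partner <- st$partner; x <- st$x; y <- st$y
    }
  }

  frames <- array(0L, dim = c(ny, nx, nf))
  truth_list <- vector("list", nf)
  for (f in 0:(nf - 1L)) {
    bleached <- t_bleach <= (f + 0.5) * dt
    emit <- which(!bleached)
    frames[, , f + 1L] <- render_frame(
      x[emit], y[emit], rep(config$photons_per_spot, length(emit)),
      nx, ny, config$pixel_size, sigma_um,
      config$background_mean, config$background_noise_sd)
    truth_list[[f + 1L]] <- data.frame(
      particle_id = seq_len(n), frame = f, x_um = x, y_um = y,
      bleached = bleached, partner_id = partner, mobile = mobile,
      wrap_x = cum_wx, wrap_y = cum_wy)
    # advance to the next frame
    mv <- step_diffusion(x, y, partner, mobile, config$d_lat, dt, W, H)
    x <- mv$x; y <- mv$y
    cum_wx <- cum_wx + mv$wrap_x
    cum_wy <- cum_wy + mv$wrap_y
    if (config$dimer_on_rate > 0 || any(!is.na(partner))) {
      st <- step_dimer_kinetics(x, y, partner, mobile,
                                config$dimer_on_rate, config$dimer_off_rate,
                                dt, config$capture_dist, W, H)
      partner <- st$partner; x <- st$x; y <- st$y
    }
  }
  truth <- do.call(rbind, truth_list)
  truth <- truth[order(truth$particle_id, truth$frame), ]
  rownames(truth) <- NULL
  structure(list(movie = movie_stack(frames, config$pixel_size, dt),
                 truth = truth, config = config),
            class = "tirf_sim")
}

#' @export
print.tirf_sim <- function(x, ...) {
  cat("Simulated TIRF recording\n")
  print(x$movie)
  cat(sprintf("  %d particles, seed %d\n",
              length(unique(x$truth$particle_id)), x$config$rng_seed))
  invisible(x)
}

#' Unwrap periodic ground-truth trajectories
#'
#' Converts wrapped positions plus recorded wrap counts back to continuous
#' trajectories, so that ground-truth displacements can be computed across
#' box boundaries.
#'
#' @param truth ground-truth table from [simulate_movie()].
#' @param config the matching [movie_config()].
#' @return `truth` with `x_um` and `y_um` replaced by unwrapped coordinates.
#' @export
unwrap_truth <- function(truth, config) {
  truth$x_um <- truth$x_um + truth$wrap_x * config$field_width
  truth$y_um <- truth$y_um + truth$wrap_y * config$field_height
  truth
}

#' Simulate reversible monomer-dimer kinetics of membrane receptors
#'
#' Spatial Monte Carlo simulation of a 2-d monomer-dimer equilibrium:
#' receptors diffuse in a periodic box, monomer pairs within
#' `capture_dist` associate with the discrete-time probability implied by
#' the mass-action rate constant `k_on` (um^2/s), and dimers dissociate at
#' `k_off` (s^-1). Used to study how the equilibrium dimer fraction depends
#' on surface density, and as a ground-truth oracle for dimer dwell times
#' (mean dwell = 1/k_off).
#'
#' @param density receptor density, um^-2.
#' @param k_on association rate constant, um^2/s.
#' @param k_off dissociation rate, s^-1.
#' @param duration simulated time, s.
#' @param dt time step, s.
#' @param box_side side of the periodic box, um.
#' @param d_lat diffusion coefficient, um^2/s.
#' @param capture_dist association capture distance, um.
#' @param seed integer seed.
#' @return data.frame of class `"dimer_timeline"` with columns `time_s`,
#'   `n_monomer`, `n_dimer` (number of dimer pairs). Attributes:
#'   `dwell_times` (completed dimer lifetimes, s) and `dimer_fraction`
#'   (mean fraction of particles in dimers over the second half of the
#'   run).
#' @export
simulate_dimer_kinetics <- function(density, k_on, k_off, duration,
                                    dt = 0.01, box_side = 10, d_lat = 0.15,
                                    capture_dist = 0.05, seed = 1L) {
  for (nm in c("density", "k_on", "k_off", "duration", "dt", "box_side"))
    stop_if_not_scalar_number(get(nm), nm, min = 0)
  set.seed(as.integer(seed))
  n_steps <- floor(duration / dt)
  if (n_steps == 0L) {
    out <- data.frame(time_s = numeric(0), n_monomer = integer(0),
                      n_dimer = integer(0))
    attr(out, "dwell_times") <- numeric(0)
    attr(out, "dimer_fraction") <- NA_real_
    class(out) <- c("dimer_timeline", "data.frame")
    return(out)
  }
  n <- max(0L, round(density * box_side^2))
  x <- runif(n, 0, box_side); y <- runif(n, 0, box_side)
  partner <- rep(NA_integer_, n)
  mobile <- rep(TRUE, n)
  born <- rep(NA_real_, n)  # association time of the pair (lead index)
  dwells <- numeric(0)
  tl_time <- (0:n_steps) * dt
  tl_dimer <- integer(n_steps + 1L)
  for (s in seq_len(n_steps)) {
    mv <- step_diffusion(x, y, partner, mobile, d_lat, dt,
                         box_side, box_side)
    x <- mv$x; y <- mv$y
    st <- step_dimer_kinetics(x, y, partner, mobile, k_on, k_off, dt,
                              capture_dist, box_side, box_side)
    x <- st$x; y <- st$y
    now <- s * dt
    if (length(st$events$dissoc)) {
      done <- st$events$dissoc
      dwells <- c(dwells, now - born[done])
      born[done] <- NA_real_
    }
    if (length(st$events$assoc)) born[st$events$assoc] <- now
    partner <- st$partner
    tl_dimer[s + 1L] <- sum(!is.na(partner)) %/% 2L
  }
  out <- data.frame(time_s = tl_time, n_dimer = tl_dimer,
                    n_monomer = n - 2L * tl_dimer)
  late <- out$time_s >= duration / 2
  attr(out, "dwell_times") <- dwells
  attr(out, "dimer_fraction") <-
    if (n > 0) mean(2 * out$n_dimer[late] / n) else NA_real_
  class(out) <- c("dimer_timeline", "data.frame")
  out
}
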