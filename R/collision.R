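#' Configuration of the receptor-channel collision simulation
#'
#' Parameters of the 2-d Monte Carlo encounter simulation between two
#' mobile membrane species (receptors and channels). An encounter is scored
#' when a receptor-channel pair first approaches within the collision
#' radius `b` from outside; the pair must then separate beyond
#' `escape_radius` before it can score again, which makes "a collision" a
#' discrete diffusive encounter rather than a burst of sub-step contacts.
#' Because a 2-d random walk is recurrent, a pair parked just outside the
#' capture disc re-crosses it many times before truly separating; the
#' re-arming distance therefore defaults to 0.3 um -- the scale at which
#' two molecules become optically distinguishable again, comparable to the
#' inter-partner spacing at the densities of interest -- so that one
#' diffusive encounter is counted once.
#' The time step must satisfy `sqrt(2 * (d_r + d_g) * dt) <= b / 2` so
#' that pairs cannot step across the capture disc undetected; the default
#' (`time_step = NULL`) uses the largest step allowed by that rule.
#'
#' @param receptor_density,channel_density surface densities, um^-2.
#' @param d_r,d_g diffusion coefficients of the two species, um^2/s.
#' @param collision_radius capture distance b, um (default 0.006 = 6 nm,
#'   molecular contact between a receptor and a channel).
#' @param escape_radius re-arming distance, um (default 0.3).
#' @param box_side periodic box side, um; the default is chosen so the box
#'   holds at least 100 receptors (and is at least 5 um).
#' @param time_step integration step, s, or `NULL` for the largest step
#'   satisfying the no-tunneling constraint.
#' @param duration simulated time, s.
#' @param seed integer seed for the simulation's random number stream.
#' @return list of class `"collision_config"`.
#' @examples
#' collision_config(receptor_density = 3, channel_density = 3,
#'                  d_r = 1, d_g = 1, duration = 0.5)
#' @export
collision_config <- function(receptor_density = 3, channel_density = 3,
                             d_r = 1, d_g = 1, collision_radius = 0.006,
                             escape_radius = 0.3,
                             box_side = NULL, time_step = NULL,
                             duration = 2, seed = 1L) {
  stop_if_not_scalar_number(receptor_density, "receptor_density", 0)
  stop_if_not_scalar_number(channel_density, "channel_density", 0)
  stop_if_not_scalar_number(d_r, "d_r", 0)
  stop_if_not_scalar_number(d_g, "d_g", 0)
  stop_if_not_scalar_number(collision_radius, "collision_radius", 0,
                            allow_zero = FALSE)
  stop_if_not_scalar_number(duration, "duration", 0, allow_zero = FALSE)
  if (escape_radius <= collision_radius)
    stop("'escape_radius' must exceed 'collision_radius'", call. = FALSE)
  if (is.null(box_side)) {
    box_side <- max(5, ceiling(10 * sqrt(100 / max(receptor_density, 0.01)))
                    / 10)
  }
  if (box_side < 10 * collision_radius)
    stop("'box_side' must be much larger than the collision radius",
         call. = FALSE)
  d_rel <- d_r + d_g
  dt_max <- if (d_rel > 0) collision_radius^2 / (8 * d_rel) else Inf
  if (is.null(time_step)) time_step <- min(dt_max, duration)
  if (sqrt(2 * d_rel * time_step) > collision_radius / 2 + 1e-12)
    stop("time step violates the no-tunneling constraint ",
         "sqrt(2*(d_r+d_g)*dt) <= b/2; decrease 'time_step'",
         call. = FALSE)
  structure(list(receptor_density = receptor_density,
                 channel_density = channel_density, d_r = d_r, d_g = d_g,
                 collision_radius = collision_radius,
                 escape_radius = escape_radius, box_side = box_side,
                 time_step = time_step, duration = duration,
                 seed = as.integer(seed)),
            class = "collision_config")
}

#' Simulate receptor-channel collisions
#'
#' Runs the 2-d Monte Carlo encounter simulation defined by a
#' [collision_config()]. Reports the mean per-receptor encounter rate, the
#' mean first-encounter latency over receptors, and their Monte Carlo
#' standard errors. Receptors with no encounter within the simulated
#' duration are right-censored and excluded from the latency mean (with
#' their number reported).
#'
#' @param config a [collision_config()].
#' @return list of class `"collision_result"`: `rate` (encounters per
#'   receptor per second), `rate_se`, `latency_s` (mean first-encounter
#'   time), `latency_se`, `n_censored`, `encounters`, `n_receptors`,
#'   `n_channels`, `particle_seconds` and `config`.
#' @export
simulate_collisions <- function(config) {
  stopifnot(inherits(config, "collision_config"))
  n_r <- max(1L, as.integer(round(config$receptor_density *
                                    config$box_side^2)))
  n_g <- max(0L, as.integer(round(config$channel_density *
                                    config$box_side^2)))
  res <- collide_cpp(n_r, n_g, config$box_side, config$d_r, config$d_g,
                     config$collision_radius, config$escape_radius,
                     config$time_step, config$duration, config$seed,
                     rebuild_every = 64L)
  per <- res$enc_per_receptor / config$duration
  lat <- res$first_latency
  n_cens <- sum(is.na(lat))
  if (n_cens > 0)
    warning(sprintf("%d receptor(s) had no encounter within %g s; ",
                    n_cens, config$duration),
            "latency estimate is right-censored")
  lat_ok <- lat[!is.na(lat)]
  structure(list(
    rate = mean(per),
    rate_se = sd(per) / sqrt(n_r),
    latency_s = if (length(lat_ok)) mean(lat_ok) else NA_real_,
    latency_se = if (length(lat_ok) > 1L)
      sd(lat_ok) / sqrt(length(lat_ok)) else NA_real_,
    n_censored = n_cens,
    encounters = res$encounters,
    n_receptors = as.integer(n_r), n_channels = as.integer(n_g),
    particle_seconds = n_r * config$duration,
    config = config), class = "collision_result")
}

#' @export
print.collision_result <- function(x, ...) {
  cat(sprintf(paste0(
    "collision_result: %.3g +/- %.2g encounters/receptor/s\n",
    "  first-encounter latency %.3g +/- %.2g s (%d censored)\n",
    "  %d receptors, %d channels, %g s simulated\n"),
    x$rate, x$rate_se, x$latency_s, x$latency_se, x$n_censored,
    x$n_receptors, x$n_channels, x$config$duration))
  invisible(x)
}

#' Collision simulation averaged over independent seeds
#'
#' @param config a [collision_config()]; its `seed` field seeds the first
#'   replicate, subsequent replicates increment it.
#' @param n_seeds number of independent replicates.
#' @return list with `rate`, `rate_se` (SE over replicates), `latency_s`,
#'   `latency_se`, `per_seed` (data.frame of replicate results), and
#'   `config`.
#' @export
collision_ensemble <- function(config, n_seeds = 5L) {
  stopifnot(inherits(config, "collision_config"))
  runs <- lapply(seq_len(n_seeds) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    simulate_collisions(cfg)
  })
  rates <- vapply(runs, `[[`, numeric(1), "rate")
  lats <- vapply(runs, `[[`, numeric(1), "latency_s")
  list(rate = mean(rates),
       rate_se = if (n_seeds > 1L) sd(rates) / sqrt(n_seeds) else NA_real_,
       latency_s = mean(lats),
       latency_se = if (n_seeds > 1L) sd(lats) / sqrt(n_seeds) else NA_real_,
       per_seed = data.frame(seed = config$seed + seq_len(n_seeds) - 1L,
                             rate = rates, latency_s = lats),
       config = config)
}

#' Mean first-encounter latency between a receptor and a channel
#'
#' Convenience wrapper around [simulate_collisions()] that returns the mean
#' waiting time (s) from the start of the simulation to a receptor's first
#' encounter with any channel. Under Poisson-like encounter statistics this
#' is approximately the reciprocal of the encounter rate.
#'
#' @param config a [collision_config()].
#' @return mean first-encounter latency, seconds.
#' @export
mean_first_encounter_latency <- function(config) {
  simulate_collisions(config)$latency_s
}

#' Two-dimensional diffusion-limited encounter rate (closed form)
#'
#' Leading-order time-dependent Smoluchowski rate for irreversible capture
#' in two dimensions: `k(t) = 4 * pi * D_rel / ln(4 * D_rel * t / b^2)`,
#' multiplied by the partner density. In 2-d the steady rate vanishes only
#' logarithmically, so evaluated at an observation horizon `t` this is an
#' order-of-magnitude comparator for the Monte Carlo simulation rather
#' than an exact result.
#'
#' @param d_rel summed diffusion coefficient of the pair, um^2/s.
#' @param b capture radius, um.
#' @param rho partner density, um^-2.
#' @param t observation horizon, s (must exceed `b^2 / (4 * d_rel)`).
#' @return encounter rate, s^-1.
#' @examples
#' smoluchowski_rate_2d(2, 0.006, 3, 1)  # ~6 per second
#' @export
smoluchowski_rate_2d <- function(d_rel, b, rho, t) {
  stop_if_not_scalar_number(d_rel, "d_rel", 0, allow_zero = FALSE)
  stop_if_not_scalar_number(b, "b", 0, allow_zero = FALSE)
  stop_if_not_scalar_number(rho, "rho", 0)
  stop_if_not_scalar_number(t, "t", 0, allow_zero = FALSE)
  arg <- 4 * d_rel * t / b^2
  if (arg <= 1)
    stop("observation horizon too short: 4*d_rel*t/b^2 must exceed 1",
         call. = FALSE)
  4 * pi * d_rel * rho / log(arg)
}
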