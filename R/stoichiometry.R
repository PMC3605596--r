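#' Extract the intensity trace of one tracked spot
#'
#' For every frame of a track, averages the camera counts over a
#' `window x window` pixel region centered on the rounded tracked position
#' and subtracts the frame-wide background (median counts/pixel), giving
#' mean background-subtracted counts per pixel (the integrated spot count
#' is `window^2` times this value). With `extend_frames > 0` the window is
#' also read at the final tracked position for frames after the track ends,
#' so that the terminal drop to background (photobleaching) appears in the
#' trace. Frames whose window would be clipped by the image edge are
#' flagged and excluded from the values.
#'
#' @param movie a [movie_stack()].
#' @param track rows of a track table for a single track.
#' @param window window side in pixels (odd).
#' @param extend_frames extra frames appended after the last tracked frame.
#' @return data.frame of class `"intensity_trace"` with columns `frame`,
#'   `intensity` (mean counts/pixel above background), `tracked` and
#'   `flagged`.
#' @export
extract_intensity_trace <- function(movie, track, window = 5L,
                                    extend_frames = 0L) {
  stopifnot(inherits(movie, "movie_stack"))
  if (length(unique(track$track_id)) > 1L)
    stop("'track' must contain a single track", call. = FALSE)
  px <- attr(movie, "pixel_size")
  d <- dim(movie)
  half <- (as.integer(window) - 1L) %/% 2L
  track <- track[order(track$frame), , drop = FALSE]
  nf_total <- d[3L]
  last <- nrow(track)
  ext <- integer(0)
  if (extend_frames > 0L) {
    first_ext <- track$frame[last] + 1L
    last_ext <- min(track$frame[last] + extend_frames, nf_total - 1L)
    if (first_ext <= last_ext) ext <- seq(first_ext, last_ext)
  }
  frames <- c(track$frame, ext)
  xs <- c(track$x_um, rep(track$x_um[last], length(ext)))
  ys <- c(track$y_um, rep(track$y_um[last], length(ext)))
  vals <- numeric(length(frames))
  flagged <- logical(length(frames))
  for (r in seq_along(frames)) {
    img <- get_frame(movie, frames[r])
    j0 <- round(xs[r] / px) + 1L
    i0 <- round(ys[r] / px) + 1L
    if (i0 - half < 1L || i0 + half > d[1L] ||
        j0 - half < 1L || j0 + half > d[2L]) {
      flagged[r] <- TRUE
      vals[r] <- NA_real_
      next
    }
    win <- img[(i0 - half):(i0 + half), (j0 - half):(j0 + half)]
    vals[r] <- mean(win) - median(img)
  }
  out <- data.frame(frame = frames, intensity = vals,
                    tracked = c(rep(TRUE, last), rep(FALSE, length(ext))),
                    flagged = flagged)
  out <- out[!out$flagged | out$tracked, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("intensity_trace", "data.frame")
  out
}

#' Three-point running median smoothing
#'
#' Removes single-frame spikes while preserving genuine stepwise intensity
#' changes. Endpoints are passed through unchanged.
#'
#' @param x numeric vector (length >= 3) or an intensity trace.
#' @return smoothed vector of the same length.
#' @examples
#' median_smooth(c(5, 5, 50, 5, 5))  # spike removed
#' @export
median_smooth <- function(x) {
  if (is.data.frame(x)) x <- x$intensity
  if (length(x) < 3L) stop("need length >= 3", call. = FALSE)
  as.numeric(stats::runmed(x, 3L, endrule = "keep"))
}

#' Detect stepwise intensity transitions in a trace
#'
#' Computes a central first derivative of the trace over a running
#' `window`-point region (the mean of the `(window-1)/2` frames ahead minus
#' the mean of the frames behind, so a clean step responds with its full
#' height); local extrema of the derivative whose magnitude exceeds
#' `threshold_sd` times the robust (MAD-based) derivative noise are taken
#' as transitions, and the fitted levels are the means of the intensity
#' values between consecutive transitions. Because a single derivative
#' sample has limited signal-to-noise, candidate peaks are collected at 70%
#' of the threshold and each candidate is then validated by the separation
#' of the mean levels on its two sides (a z-test at `threshold_sd`, using
#' up to 10 frames per side); levels pool many frames, so genuine steps
#' validate with a large margin while derivative noise excursions are
#' pruned. A transition at frame index `t` (1-based) separates the level
#' ending at `t` from the level starting at `t + 1`.
#'
#' @param trace numeric vector or intensity trace data.frame.
#' @param window derivative window, odd, >= 3 (5 matches a least-squares
#'   slope over two frames each side).
#' @param threshold_sd detection threshold in robust derivative SDs.
#' @param min_gap minimum spacing between transitions, frames.
#' @return list of class `"step_fit"` with `transitions` (frame indices,
#'   1-based, possibly empty), `levels` (mean intensity of each piece),
#'   `level_start` (first index of each piece) and `noise_sd`.
#' @export
detect_steps <- function(trace, window = 5L, threshold_sd = 4,
                         min_gap = 3L) {
  x <- if (is.data.frame(trace)) trace$intensity else as.numeric(trace)
  x <- x[is.finite(x)]
  n <- length(x)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  if (n < window) {
    return(structure(list(transitions = integer(0), levels = mean(x),
                          level_start = 1L, noise_sd = NA_real_),
                     class = "step_fit"))
  }
  h <- (window - 1L) %/% 2L
  # pad by edge replication so edge frames get a derivative too
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  deriv <- vapply(seq_len(n), function(i) {
    c0 <- i + h  # index of frame i in the padded trace
    mean(xp[(c0 + 1L):(c0 + h)]) - mean(xp[(c0 - h):(c0 - 1L)])
  }, numeric(1))
  # Robust derivative-noise scale from lag-3 trace differences (MAD-based,
  # so occasional genuine steps do not inflate it; lag 3 clears the
  # correlation length of the 3-point median filter). The factor 1.2 maps
  # the lag-3 difference scale to the derivative's noise SD, calibrated on
  # median-filtered Gaussian noise; for unfiltered traces it overestimates
  # by ~20%, which only makes detection slightly conservative.
  noise <- if (n > 3L)
    1.2 * stats::mad(x[-(1:3)] - x[seq_len(n - 3L)]) / sqrt(2)
  else robust_sd(deriv)
  if (!is.finite(noise) || noise == 0) noise <- .Machine$double.eps
  mag <- abs(deriv)
  thresh <- 0.5 * threshold_sd * noise  # candidate threshold; see below
  is_peak <- mag > thresh &
    mag >= c(-Inf, mag[-n]) & mag >= c(mag[-1L], -Inf)
  peaks <- which(is_peak)
  # enforce minimum spacing, keeping the strongest peak of each cluster
  if (length(peaks) > 1L) {
    keep <- logical(length(peaks))
    ord <- order(mag[peaks], decreasing = TRUE)
    taken <- integer(0)
    for (p in ord) {
      if (!length(taken) || all(abs(peaks[p] - taken) >= min_gap)) {
        keep[p] <- TRUE
        taken <- c(taken, peaks[p])
      }
    }
    peaks <- sort(peaks[keep])
  }
  # a peak at index i marks the change between levels [.., i] and [i+1, ..];
  # the slope filter peaks at the last frame of the old level for an ideal
  # step, but on noisy data it can land one frame into the new level, so
  # refine each transition to the split that maximizes the level contrast
  trans <- integer(0)
  for (p in peaks) {
    lo <- max(1L, p - 1L); hi <- min(n - 1L, p + 1L)
    best <- NA_integer_; best_gap <- -Inf
    for (tr in lo:hi) {
      left <- x[max(1L, tr - 4L):tr]
      right <- x[(tr + 1L):min(n, tr + 5L)]
      gap <- abs(mean(left) - mean(right))
      if (gap > best_gap) { best_gap <- gap; best <- tr }
    }
    trans <- c(trans, best)
  }
  trans <- sort(unique(trans[trans >= 1L & trans < n]))
  # validate each candidate by the separation of the levels on its sides;
  # the SE of a level mean is inflated by 1.5 because median filtering
  # leaves neighboring samples positively correlated
  sigma_x <- 1.5 * noise / 1.2  # trace noise scale (undo the deriv factor)
  repeat {
    if (!length(trans)) break
    bounds <- c(0L, trans, n)
    ok <- vapply(seq_along(trans), function(k) {
      tr <- trans[k]
      l0 <- max(bounds[k] + 1L, tr - 9L)
      r1 <- min(bounds[k + 2L], tr + 10L)
      left <- x[l0:tr]
      right <- x[(tr + 1L):r1]
      se <- sigma_x * sqrt(1 / length(left) + 1 / length(right))
      abs(mean(left) - mean(right)) > threshold_sd * max(se,
                                                         .Machine$double.eps)
    }, logical(1))
    if (all(ok)) break
    trans <- trans[ok]
  }
  starts <- c(1L, trans + 1L)
  ends <- c(trans, n)
  levels <- vapply(seq_along(starts),
                   function(k) mean(x[starts[k]:ends[k]]), numeric(1))
  structure(list(transitions = trans, levels = levels,
                 level_start = starts, noise_sd = noise),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("step_fit: %d transition(s) at {%s}; levels {%s}\n",
              length(x$transitions),
              paste(x$transitions, collapse = ", "),
              paste(sprintf("%.3g", x$levels), collapse = ", ")))
  invisible(x)
}

#' Classify an intensity trajectory by its photobleaching pattern
#'
#' Deterministic typing of a fitted step trace against a calibrated
#' single-fluorophore ("unit") intensity. Each level is mapped to the
#' nearest integer number of units; a level matches `n` units when it lies
#' within `tol` (default 35%) of `n * unit_intensity`, and matches
#' background when it is below `tol * unit_intensity`. Types follow the
#' standard single-molecule taxonomy: a constant 1-unit level ending in a
#' single drop to background is a monomer bleaching in one step
#' (`"type1"`); two successive 1-unit drops (2 units, then 1, then
#' background) are a dimer bleaching twice (`"type2"`); a 1-unit level that
#' rises to 2 units and later falls to background reports reversible dimer
#' formation (`"type3"`). Any other trace that alternates between the 1-
#' and 2-unit levels is still evidence of a dimer and is binned as
#' `"dimer_other"`. Traces reaching 3 or more units are flagged
#' `"higher_oligomer"`; everything else (including censored traces that
#' never return to background) is `"unclassified"`.
#'
#' @param fit a [detect_steps()] result.
#' @param unit_intensity calibrated intensity of a single fluorophore, in
#'   the units of the trace (> 0).
#' @param tol relative tolerance for matching a level to a unit multiple.
#' @return character: one of `"type1"`, `"type2"`, `"type3"`,
#'   `"dimer_other"`, `"higher_oligomer"`, `"unclassified"`.
#' @export
classify_trajectory <- function(fit, unit_intensity, tol = 0.35) {
  stopifnot(inherits(fit, "step_fit"))
  stop_if_not_scalar_number(unit_intensity, "unit_intensity", 0,
                            allow_zero = FALSE)
  lv <- fit$levels
  units <- round(lv / unit_intensity)
  ok <- abs(lv - units * unit_intensity) <= tol * unit_intensity
  if (!all(ok) || any(units < 0)) return("unclassified")
  if (any(units >= 3)) return("higher_oligomer")
  # collapse consecutive equal unit counts (levels the tolerance merged)
  u <- units[c(TRUE, diff(units) != 0)]
  if (length(u) < 2L || u[length(u)] != 0) return("unclassified")
  body <- u[-length(u)]
  if (identical(body, c(1))) return("type1")
  if (identical(body, c(2, 1))) return("type2")
  if (identical(body, c(1, 2))) return("type3")
  if (all(body %in% c(1, 2)) && max(body) == 2) return("dimer_other")
  "unclassified"
}

#' Intensity histogram with monomer-peak calibration
#'
#' Estimates the single-fluorophore ("monomer") unit intensity as the mode
#' of the spot-intensity distribution (kernel density peak) and reports the
#' fraction of measurements brighter than `tail_factor` times the mode.
#' With a mostly monomeric population the mode sits at the one-fluorophore
#' intensity and the bright tail estimates the instantaneous fraction of
#' coincident/dimeric spots.
#'
#' @param intensities numeric vector of spot intensities (>= 100 values).
#' @param tail_factor multiple of the mode above which a measurement counts
#'   as part of the bright tail.
#' @return list with `mode` (unit intensity), `tail_fraction`, and `n`.
#' @export
intensity_histogram <- function(intensities, tail_factor = 1.5) {
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < 100L)
    stop("need >= 100 intensity measurements", call. = FALSE)
  dens <- stats::density(intensities, n = 512)
  mode <- dens$x[which.max(dens$y)]
  tail_fraction <- mean(intensities > tail_factor * mode)
  list(mode = mode, tail_fraction = tail_fraction, n = length(intensities))
}

#' Chance-coincidence null model for apparent dimer tracks
#'
#' Monte Carlo null for the rate at which independently diffusing receptors
#' would produce apparent dimer trajectories purely by chance overlap of
#' their diffraction-limited images. Particles diffuse independently in a
#' periodic box at the given density; a track shows a chance coincidence
#' when some other particle stays within `coincidence_dist` of it
#' continuously for at least `min_overlap_s` (sustained proximity is what
#' reads out as a stable doubled-intensity level; the default 1 s matches
#' the dwell of genuine dimer episodes, use one frame interval for an
#' instantaneous criterion). Returns the fraction of tracks containing at
#' least one such interval.
#'
#' @param density particle density, um^-2.
#' @param d_lat diffusion coefficient, um^2/s.
#' @param coincidence_dist center-to-center coincidence distance, um
#'   (~ the PSF radius; 0.3 um by default).
#' @param duration track duration, s.
#' @param frame_interval frame interval, s.
#' @param min_overlap_s minimum sustained-coincidence duration, s.
#' @param box_side periodic box side, um.
#' @param seed integer seed.
#' @return list with `fraction`, `se` (binomial Monte Carlo SE) and
#'   `n_tracks`.
#' @export
coincidence_null <- function(density, d_lat, coincidence_dist = 0.3,
                             duration = 1, frame_interval = 0.02,
                             min_overlap_s = 1, box_side = 12, seed = 1L) {
  stop_if_not_scalar_number(density, "density", 0)
  stop_if_not_scalar_number(d_lat, "d_lat", 0)
  set.seed(as.integer(seed))
  n <- round(density * box_side^2)
  if (n < 2L)
    return(list(fraction = 0, se = 0, n_tracks = n))
  nf <- max(1L, round(duration / frame_interval))
  need <- max(1L, round(min_overlap_s / frame_interval))
  x <- runif(n, 0, box_side); y <- runif(n, 0, box_side)
  s <- sqrt(2 * d_lat * frame_interval)
  run <- integer(n)      # current consecutive frames with a close neighbor
  hit <- logical(n)
  for (f in seq_len(nf)) {
    if (f > 1L) {
      x <- (x + rnorm(n, 0, s)) %% box_side
      y <- (y + rnorm(n, 0, s)) %% box_side
    }
    dx <- min_image(outer(x, x, "-"), box_side)
    dy <- min_image(outer(y, y, "-"), box_side)
    d2 <- dx * dx + dy * dy
    diag(d2) <- Inf
    close <- apply(d2, 1L, min) < coincidence_dist^2
    run <- ifelse(close, run + 1L, 0L)
    hit <- hit | run >= need
  }
  p <- mean(hit)
  list(fraction = p, se = sqrt(p * (1 - p) / n), n_tracks = n)
}
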