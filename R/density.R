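#' Receptor surface density by direct spot counting
#'
#' Counts detected spots per frame over the early part of a recording and
#' divides by the membrane footprint area. Direct counting is only reliable
#' while spots are sparse enough that their diffraction-limited images
#' rarely overlap; above `direct_limit` (default 0.8 um^-2) the estimate is
#' flagged as unreliable (overlapping point spread functions cause
#' undercounting).
#'
#' @param spots data.frame of detections with a `frame` column (e.g. from
#'   [detect_movie()]), or an integer vector of per-frame counts.
#' @param footprint_area membrane footprint area, um^2 (> 0).
#' @param n_early number of early frames to average over (default: all
#'   frames present).
#' @param direct_limit density above which direct counting is flagged.
#' @return list of class `"density_estimate"` with `rho` (um^-2), `se`
#'   (Poisson standard error), `method = "direct"`, `area`, `n_frames` and
#'   `flagged`.
#' @export
count_density <- function(spots, footprint_area, n_early = NULL,
                          direct_limit = 0.8) {
  stop_if_not_scalar_number(footprint_area, "footprint_area", min = 0,
                            allow_zero = FALSE)
  if (is.data.frame(spots)) {
    if (!"frame" %in% names(spots))
      stop("'spots' must have a 'frame' column", call. = FALSE)
    frames <- sort(unique(spots$frame))
    counts <- as.vector(table(factor(spots$frame, levels = frames)))
  } else {
    counts <- as.numeric(spots)
  }
  if (!is.null(n_early)) counts <- head(counts, n_early)
  if (length(counts) == 0L) stop("no frames to count", call. = FALSE)
  n_f <- length(counts)
  rho <- mean(counts) / footprint_area
  # counts in successive frames are the same molecules, so the effective
  # number of independent observations is ~1 cell; report per-frame Poisson SE
  se <- sqrt(mean(counts)) / footprint_area
  structure(list(rho = rho, se = se, method = "direct",
                 area = footprint_area, n_frames = n_f,
                 flagged = rho > direct_limit),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("rho = %.3g +/- %.2g um^-2 (%s, %g um^2%s)\n", x$rho, x$se,
              x$method, x$area,
              if (isTRUE(x$flagged)) ", FLAGGED: above direct-count limit"
              else ""))
  invisible(x)
}

#' Fit the bulk photobleaching rate from field intensity decay
#'
#' Least-squares fit of `I(t) = I0 * exp(-k * t) + offset` to the summed (or
#' mean) field intensity over time. Used to back-extrapolate spot counts to
#' the start of illumination when the initial density is too high to count
#' directly.
#'
#' @param time time points, seconds (>= 10).
#' @param intensity summed field intensity at each time point.
#' @return list with `k_bleach` (per second), `i0`, `offset`, and
#'   `converged`.
#' @export
fit_bleach_rate <- function(time, intensity) {
  if (length(time) != length(intensity))
    stop("'time' and 'intensity' must have equal length", call. = FALSE)
  if (length(time) < 10L) stop("need >= 10 time points", call. = FALSE)
  trend <- suppressWarnings(stats::cor(time, intensity))
  if (is.na(trend) || trend >= 0) {
    warning("intensity does not decay with time; k_bleach set to 0")
    return(list(k_bleach = 0, i0 = mean(intensity), offset = 0,
                converged = FALSE))
  }
  off0 <- min(intensity)
  amp0 <- max(intensity) - off0
  pos <- intensity - off0 + amp0 * 1e-3
  k0 <- -unname(coef(lm(log(pos) ~ time))[2L])
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(time)
  fit <- tryCatch(
    nls(intensity ~ i0 * exp(-k * time) + off,
        start = list(i0 = amp0, k = k0, off = off0),
        # scaleOffset keeps the convergence test stable on near-exact data
        control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                     warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(k_bleach = k0, i0 = amp0, offset = off0, converged = FALSE))
  p <- coef(fit)
  list(k_bleach = max(0, unname(p["k"])), i0 = unname(p["i0"]),
       offset = unname(p["off"]), converged = TRUE)
}

#' Initial density by photobleaching back-extrapolation
#'
#' Estimates an initial spot density that is too high to count directly by
#' waiting until photobleaching has thinned the field below the countable
#' limit and back-extrapolating the late-time counts with the measured bulk
#' bleaching rate. With single-fluorophore spots the count decays as
#' `N(t) = N0 * exp(-k_bleach * t)`, so the Poisson maximum-likelihood
#' estimate pooled over the usable late frames is
#' `rho0 = sum(N_i) / (area * sum(exp(-k * t_i)))`.
#'
#' @param time frame times, seconds.
#' @param counts spot counts per frame.
#' @param k_bleach bulk photobleaching rate, per second (from
#'   [fit_bleach_rate()]).
#' @param footprint_area membrane footprint area, um^2.
#' @param count_limit only frames after the (running-mean smoothed)
#'   observed density first drops to this level are used, um^-2.
#' @return list of class `"density_estimate"` with `rho` (the extrapolated
#'   initial density), `se`, `method = "bleach_extrapolated"`, `area`,
#'   `n_frames` (usable late frames) and `flagged`.
#' @export
bleach_extrapolate <- function(time, counts, k_bleach, footprint_area,
                               count_limit = 0.5) {
  stop_if_not_scalar_number(footprint_area, "footprint_area", min = 0,
                            allow_zero = FALSE)
  if (length(time) != length(counts))
    stop("'time' and 'counts' must have equal length", call. = FALSE)
  if (k_bleach <= 0) {
    warning("k_bleach <= 0; falling back to direct counting")
    return(count_density(counts, footprint_area))
  }
  rho_t <- counts / footprint_area
  k_run <- min(5L, length(rho_t))
  smooth <- stats::filter(rho_t, rep(1 / k_run, k_run), sides = 1)
  # usable frames start after the *last* time the smoothed observed
  # density exceeds the limit (early frames can undercount so badly that
  # the observed density dips below the limit while the field is still
  # crowded)
  above <- which(!is.na(smooth) & smooth > count_limit)
  start <- if (length(above)) max(above) + 1L else 1L
  if (is.na(start) || start > length(time))
    stop("density never decays below 'count_limit'; record longer or raise ",
         "the limit", call. = FALSE)
  use <- seq(start, length(time))
  denom <- footprint_area * sum(exp(-k_bleach * time[use]))
  rho0 <- sum(counts[use]) / denom
  se <- sqrt(sum(counts[use])) / denom
  structure(list(rho = rho0, se = se, method = "bleach_extrapolated",
                 area = footprint_area, n_frames = length(use),
                 flagged = FALSE),
            class = "density_estimate")
}

#' Tissue-average receptor density from heterogeneous expression
#'
#' When only a fraction of cells in a tissue express the receptor, the
#' average density over the whole tissue is the product of the expressing
#' fraction and the density on expressing cells.
#'
#' @param expressing_fraction fraction of cells expressing, in \[0, 1\].
#' @param expressing_density receptor density on expressing cells, um^-2.
#' @return tissue-average density, um^-2.
#' @examples
#' tissue_average_density(0.10, 2)  # 0.2
#' @export
tissue_average_density <- function(expressing_fraction, expressing_density) {
  stop_if_not_scalar_number(expressing_fraction, "expressing_fraction")
  stop_if_not_scalar_number(expressing_density, "expressing_density", min = 0)
  if (expressing_fraction < 0 || expressing_fraction > 1)
    stop("'expressing_fraction' must be in [0, 1]", call. = FALSE)
  expressing_fraction * expressing_density
}
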