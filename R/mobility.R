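#' Mean squared displacement versus lag time
#'
#' Computes the combined time- and ensemble-averaged MSD curve over a set of
#' trajectories: for every lag of `1..max_lag` frames, all overlapping
#' position pairs separated by exactly that many frames are pooled across
#' tracks. In two dimensions free Brownian diffusion gives
#' `MSD(dt) = 4 * D_lat * dt` (plus a constant offset from localization
#' error).
#'
#' @param tracks track table with columns `track_id`, `frame`, `x_um`,
#'   `y_um` (the format returned by [link_tracks()] / [read_tracks()]).
#' @param frame_interval time between consecutive frames, seconds.
#' @param max_lag largest lag, in frames.
#' @return data.frame of class `"msd_curve"` with columns `lag_s`,
#'   `msd_um2`, `sd_um2` (SD of the squared displacements) and `n_pairs`.
#' @examples
#' tr <- data.frame(track_id = 1, frame = 0:9, x_um = (0:9) * 0.1, y_um = 0)
#' msd_curve(tr, frame_interval = 0.02, max_lag = 4)
#' @export
msd_curve <- function(tracks, frame_interval, max_lag = 10L) {
  stop_if_not_scalar_number(frame_interval, "frame_interval", min = 0,
                            allow_zero = FALSE)
  validate_tracks(tracks)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("'max_lag' must be >= 1", call. = FALSE)
  by_track <- split(tracks[c("frame", "x_um", "y_um")], tracks$track_id)
  sq <- vector("list", max_lag)
  for (lag in seq_len(max_lag)) {
    parts <- lapply(by_track, function(tr) {
      idx <- match(tr$frame + lag, tr$frame)
      ok <- !is.na(idx)
      if (!any(ok)) return(numeric(0))
      (tr$x_um[idx[ok]] - tr$x_um[ok])^2 + (tr$y_um[idx[ok]] - tr$y_um[ok])^2
    })
    sq[[lag]] <- unlist(parts, use.names = FALSE)
  }
  n_pairs <- vapply(sq, length, integer(1))
  if (all(n_pairs == 0L))
    stop("no displacement pairs available at any lag; tracks too short",
         call. = FALSE)
  out <- data.frame(
    lag_s   = seq_len(max_lag) * frame_interval,
    msd_um2 = vapply(sq, function(v) if (length(v)) mean(v) else NA_real_,
                     numeric(1)),
    sd_um2  = vapply(sq, function(v) if (length(v) > 1L) sd(v) else NA_real_,
                     numeric(1)),
    n_pairs = n_pairs
  )
  out <- out[out$n_pairs > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Estimate the lateral diffusion coefficient from an MSD curve
#'
#' Weighted least-squares line through the first `n_fit_points` lags of the
#' MSD curve, with pair counts as weights; `D_lat` is the slope divided by 4
#' (two-dimensional diffusion). The intercept is left free so that the
#' constant offset contributed by localization error does not bias the
#' slope.
#'
#' @param curve an [msd_curve()] result.
#' @param n_fit_points number of leading lags used in the fit (>= 2).
#' @return list of class `"diffusion_estimate"` with elements `d_lat`
#'   (um^2/s), `intercept` (um^2), `se` (standard error of `d_lat`),
#'   `fit_lags_s`, and `clamped` (`TRUE` if a negative fitted slope was
#'   clamped to zero).
#' @export
fit_dlat <- function(curve, n_fit_points = 4L) {
  stopifnot(inherits(curve, "msd_curve"))
  n_fit_points <- as.integer(n_fit_points)
  if (n_fit_points < 2L) stop("'n_fit_points' must be >= 2", call. = FALSE)
  use <- head(curve, n_fit_points)
  if (nrow(use) < 2L) stop("fewer than 2 usable lags in the curve",
                           call. = FALSE)
  fit <- lm(msd_um2 ~ lag_s, data = use, weights = use$n_pairs)
  slope <- unname(coef(fit)[2L])
  se_slope <- summary(fit)$coefficients[2L, 2L]
  clamped <- FALSE
  d <- slope / 4
  if (d < 0) {
    warning("negative MSD slope; d_lat clamped to 0")
    d <- 0
    clamped <- TRUE
  }
  structure(list(d_lat = d, intercept = unname(coef(fit)[1L]),
                 se = se_slope / 4, fit_lags_s = use$lag_s,
                 clamped = clamped),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D_lat = %.4g +/- %.2g um^2/s (intercept %.3g um^2, %d lags%s)\n",
              x$d_lat, x$se, x$intercept, length(x$fit_lags_s),
              if (x$clamped) ", slope clamped" else ""))
  invisible(x)
}

#' Classify the mode of motion from the shape of an MSD curve
#'
#' Fits the anomalous-diffusion exponent alpha in `MSD ~ dt^alpha` by
#' weighted linear regression on log-log axes. Free Brownian diffusion has
#' alpha near 1; directed motion ("diffusion with flow") bends the curve
#' upward (alpha > 1), while confinement ("caged diffusion") saturates it
#' (alpha < 1).
#'
#' @param curve an [msd_curve()] result with at least 4 positive-MSD lags.
#' @param tol tolerance on alpha around 1 for calling the motion free.
#' @return list with `motion_class` (one of `"free"`, `"flow"`, `"caged"`)
#'   and the fitted `alpha`.
#' @export
classify_motion <- function(curve, tol = 0.15) {
  stopifnot(inherits(curve, "msd_curve"))
  use <- curve[is.finite(curve$msd_um2) & curve$msd_um2 > 0, , drop = FALSE]
  if (nrow(use) < 4L) stop("need >= 4 lags with positive MSD", call. = FALSE)
  fit <- lm(log(msd_um2) ~ log(lag_s), data = use, weights = use$n_pairs)
  alpha <- unname(coef(fit)[2L])
  cls <- if (alpha > 1 + tol) "flow" else if (alpha < 1 - tol) "caged"
         else "free"
  list(motion_class = cls, alpha = alpha)
}

#' Fit the temperature dependence of a diffusion coefficient
#'
#' Least-squares fit of the monoexponential model
#' `D(T) = D_ref * exp(k * (T - T_ref))` to measured (temperature, D) pairs,
#' reporting the fold change per 10 degrees C, `Q10 = exp(10 * k)`. Membrane
#' protein mobility typically roughly doubles per 10 degrees C (Q10 ~ 2).
#'
#' @param temp_c temperatures, degrees C (>= 3 points spanning >= 10 C).
#' @param d_lat diffusion coefficients, um^2/s (all > 0).
#' @param t_ref reference temperature for `D_ref`, degrees C.
#' @return list of class `"temperature_fit"` with `d_ref`, `k` (per degree
#'   C), `q10` and `t_ref`.
#' @examples
#' tt <- seq(5, 40, by = 5)
#' fit_temperature(tt, 0.1 * 2^((tt - 23) / 10))$q10  # 2
#' @export
fit_temperature <- function(temp_c, d_lat, t_ref = 23) {
  if (length(temp_c) != length(d_lat))
    stop("'temp_c' and 'd_lat' must have equal length", call. = FALSE)
  keep <- is.finite(temp_c) & is.finite(d_lat)
  if (any(d_lat[keep] <= 0)) {
    warning("non-positive D values rejected")
    keep <- keep & d_lat > 0
  }
  temp_c <- temp_c[keep]; d_lat <- d_lat[keep]
  if (length(temp_c) < 3L || diff(range(temp_c)) < 10)
    stop("need >= 3 temperature points spanning >= 10 degrees C",
         call. = FALSE)
  # log-linear fit supplies starting values; nls refines on the linear scale
  lin <- lm(log(d_lat) ~ I(temp_c - t_ref))
  start <- list(d_ref = exp(unname(coef(lin)[1L])), k = unname(coef(lin)[2L]))
  fit <- tryCatch(
    nls(d_lat ~ d_ref * exp(k * (temp_c - t_ref)), start = start),
    error = function(e) NULL)
  pars <- if (is.null(fit)) unlist(start) else coef(fit)
  structure(list(d_ref = unname(pars["d_ref"]), k = unname(pars["k"]),
                 q10 = exp(10 * unname(pars["k"])), t_ref = t_ref),
            class = "temperature_fit")
}

#' @export
print.temperature_fit <- function(x, ...) {
  cat(sprintf("D(%g C) = %.4g um^2/s, k = %.4g /C, Q10 = %.3g\n",
              x$t_ref, x$d_ref, x$k, x$q10))
  invisible(x)
}

#' Extrapolate a diffusion coefficient to another temperature
#'
#' @param fit a [fit_temperature()] result.
#' @param temp_c target temperature, degrees C.
#' @return predicted D at `temp_c`, um^2/s.
#' @export
predict_dlat <- function(fit, temp_c) {
  stopifnot(inherits(fit, "temperature_fit"))
  fit$d_ref * exp(fit$k * (temp_c - fit$t_ref))
}
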