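#' Configuration for a synthetic single-molecule TIRF movie
#'
#' Collects the physical and acquisition parameters of a simulated TIRF
#' recording of membrane receptors. Defaults emulate a typical
#' single-molecule experiment: 100 nm pixels, a diffraction-limited point
#' spread function of 300 nm FWHM, and a signal-to-noise ratio at which
#' single photobleaching steps are clearly resolved.
#'
#' @param field_width,field_height field of view, um.
#' @param pixel_size camera pixel size at the specimen, um.
#' @param frame_interval time between frames, s (50 frames/s = 0.02 s).
#' @param n_frames number of frames.
#' @param receptor_density mean receptor surface density rho, um^-2.
#' @param d_lat lateral diffusion coefficient of mobile receptors, um^2/s.
#' @param psf_fwhm full width at half maximum of the PSF, um.
#' @param photons_per_spot expected integrated photon count contributed by
#'   one unbleached fluorophore per frame.
#' @param background_mean,background_noise_sd mean and Gaussian read-noise
#'   SD of the camera background, counts/pixel.
#' @param bleach_rate photobleaching rate per fluorophore, s^-1.
#' @param dimer_on_rate two-dimensional mass-action association rate
#'   constant k_on, um^2 s^-1.
#' @param dimer_off_rate dimer dissociation rate k_off, s^-1.
#' @param capture_dist distance within which two monomers can associate, um.
#' @param immobile_fraction fraction of spots that are immobile nonspecific
#'   fluorophores, in \[0, 1\].
#' @param rng_seed integer seed; recorded in the output so any movie can be
#'   regenerated exactly.
#' @return list of class `"movie_config"`.
#' @examples
#' cfg <- movie_config(field_width = 10, field_height = 10,
#'                     receptor_density = 0.5, d_lat = 0.15, n_frames = 20)
#' @export
movie_config <- function(field_width = 20, field_height = 20,
                         pixel_size = 0.1, frame_interval = 0.02,
                         n_frames = 100, receptor_density = 1,
                         d_lat = 0.15, psf_fwhm = 0.3,
                         photons_per_spot = 600, background_mean = 100,
                         background_noise_sd = 6, bleach_rate = 0,
                         dimer_on_rate = 0, dimer_off_rate = 1,
                         capture_dist = 0.05, immobile_fraction = 0,
                         rng_seed = 1L) {
  cfg <- list(field_width = field_width, field_height = field_height,
              pixel_size = pixel_size, frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              receptor_density = receptor_density, d_lat = d_lat,
              psf_fwhm = psf_fwhm, photons_per_spot = photons_per_spot,
              background_mean = background_mean,
              background_noise_sd = background_noise_sd,
              bleach_rate = bleach_rate, dimer_on_rate = dimer_on_rate,
              dimer_off_rate = dimer_off_rate, capture_dist = capture_dist,
              immobile_fraction = immobile_fraction,
              rng_seed = as.integer(rng_seed))
  for (nm in setdiff(names(cfg), "rng_seed")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("config field '%s' must be a single finite number >= 0",
                   nm), call. = FALSE)
  }
  if (cfg$pixel_size <= 0) stop("'pixel_size' must be > 0", call. = FALSE)
  if (cfg$frame_interval <= 0)
    stop("'frame_interval' must be > 0", call. = FALSE)
  if (cfg$psf_fwhm < 2 * cfg$pixel_size)
    stop("'psf_fwhm' must be >= 2 * pixel_size for resolvable sampling",
         call. = FALSE)
  if (cfg$immobile_fraction > 1)
    stop("'immobile_fraction' must be in [0, 1]", call. = FALSE)
  if (cfg$n_frames < 1L) stop("'n_frames' must be >= 1", call. = FALSE)
  class(cfg) <- "movie_config"
  cfg
}

#' @export
print.movie_config <- function(x, ...) {
  cat(sprintf(paste0(
    "TIRF movie config: %g x %g um, %d frames @ %g s, rho = %g um^-2,\n",
    "  D = %g um^2/s, PSF FWHM %g um, %g photons/spot/frame, ",
    "k_bleach = %g /s\n"),
    x$field_width, x$field_height, x$n_frames, x$frame_interval,
    x$receptor_density, x$d_lat, x$psf_fwhm, x$photons_per_spot,
    x$bleach_rate))
  invisible(x)
}

#' Construct a calibrated movie stack
#'
#' A movie stack is a `ny x nx x n_frames` integer array of camera counts
#' with the physical calibration (pixel size and frame interval) attached.
#'
#' @param counts 3-d array of non-negative counts (`ny x nx x n_frames`).
#' @param pixel_size pixel size, um.
#' @param frame_interval frame interval, s.
#' @return array of class `"movie_stack"`.
#' @export
movie_stack <- function(counts, pixel_size, frame_interval) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (any(counts < 0)) stop("pixel counts must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(pixel_size, "pixel_size", 0, allow_zero = FALSE)
  stop_if_not_scalar_number(frame_interval, "frame_interval", 0,
                            allow_zero = FALSE)
  structure(counts, pixel_size = pixel_size, frame_interval = frame_interval,
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "movie_stack: %d x %d pixels x %d frames, %g um/pixel, %g s/frame\n",
    d[1L], d[2L], d[3L], attr(x, "pixel_size"), attr(x, "frame_interval")))
  invisible(x)
}

# Extract one frame as a plain matrix.
get_frame <- function(movie, frame) {
  stopifnot(inherits(movie, "movie_stack"))
  movie[, , frame + 1L, drop = TRUE]
}
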