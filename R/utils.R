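#' @useDynLib tirftrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median nls mad pnorm qnorm rexp rnorm rpois
#'   runif sd setNames uniroot var density
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

#' Convert Gaussian sigma to full width at half maximum (and back)
#'
#' @param sigma,fwhm width parameters, any length unit.
#' @return numeric of the same length as the input.
#' @examples
#' sigma_to_fwhm(0.1274)  # ~0.30
#' @export
sigma_to_fwhm <- function(sigma) FWHM_PER_SIGMA * sigma

#' @rdname sigma_to_fwhm
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_PER_SIGMA

# Robust noise scale: median absolute deviation scaled for Gaussian noise.
robust_sd <- function(x) stats::mad(x, constant = 1.4826, na.rm = TRUE)

stop_if_not_scalar_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < min || (!allow_zero && x == min))
    stop(sprintf("'%s' must be %s %g", name,
                 if (allow_zero) ">=" else ">", min), call. = FALSE)
  invisible(x)
}

# Wrap coordinates into [0, L) and report how many box lengths were crossed.
wrap_periodic <- function(x, L) {
  n_wrap <- floor(x / L)
  list(x = x - n_wrap * L, n_wrap = n_wrap)
}

# Minimum-image separation of coordinate differences in a periodic box.
min_image <- function(dx, L) dx - L * round(dx / L)
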