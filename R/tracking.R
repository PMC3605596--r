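#' Spot-detection parameters
#'
#' @param threshold_sd detection threshold in robust (MAD-based) noise SDs
#'   above the frame background, applied to a 3x3 box-smoothed image.
#' @param min_separation minimum center-to-center distance between accepted
#'   detections, um; defaults to the PSF FWHM, below which two emitters are
#'   not optically resolvable anyway.
#' @param window side of the square window (pixels, odd) used for the
#'   sub-pixel centroid and the integrated intensity.
#' @return list of class `"detect_params"`.
#' @export
detect_params <- function(threshold_sd = 5, min_separation = 0.3,
                          window = 5L) {
  stop_if_not_scalar_number(threshold_sd, "threshold_sd", 0,
                            allow_zero = FALSE)
  stop_if_not_scalar_number(min_separation, "min_separation", 0)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  structure(list(threshold_sd = threshold_sd,
                 min_separation = min_separation, window = window),
            class = "detect_params")
}

#' Track-linking parameters
#'
#' @param max_disp maximum frame-to-frame displacement, um. The default
#'   `NULL` resolves to `3 * sqrt(4 * d_max * frame_interval)` at linking
#'   time with `d_max = 1` um^2/s, which keeps >99% of Brownian steps of
#'   the fastest receptors reported in tissue linkable.
#' @param max_gap maximum number of missed frames bridged within a track
#'   (0: a missed detection terminates the track; blinking is not modeled).
#' @param min_length minimum number of spots for a track to be kept.
#' @param d_max diffusion coefficient (um^2/s) used for the automatic
#'   `max_disp`.
#' @return list of class `"link_params"`.
#' @export
link_params <- function(max_disp = NULL, max_gap = 0L, min_length = 5L,
                        d_max = 1) {
  if (!is.null(max_disp))
    stop_if_not_scalar_number(max_disp, "max_disp", 0, allow_zero = FALSE)
  structure(list(max_disp = max_disp, max_gap = as.integer(max_gap),
                 min_length = as.integer(min_length), d_max = d_max),
            class = "link_params")
}

# Sigma-clipped background statistics: spots only add counts, so clipping
# the bright tail recovers the background mean and noise SD even when a
# large fraction of pixels carries signal (plain MAD breaks down on
# crowded frames).
clipped_background <- function(img) {
  v <- as.vector(img)
  center <- median(v)
  s <- stats::mad(v)
  if (s == 0) return(list(mean = center, sd = 0))
  for (i in 1:3) {
    keep <- v < center + 3 * s
    center <- median(v[keep])
    s <- stats::mad(v[keep], center = center)
    if (s == 0) break
  }
  list(mean = center, sd = s)
}

# 3x3 box smoothing with edge replication, via shift-and-add.
box_smooth3 <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- img[c(1L, seq_len(ny), ny), c(1L, seq_len(nx), nx)]
  acc <- matrix(0, ny, nx)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + pad[di + seq_len(ny), dj + seq_len(nx)]
  acc / 9
}

# TRUE where a pixel is >= all 8 neighbours and > at least one of them.
local_maxima <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[1L + seq_len(ny), 1L + seq_len(nx)] <- img
  res <- matrix(TRUE, ny, nx)
  strict <- matrix(FALSE, ny, nx)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1L && dj == 1L) next
    nb <- pad[di + seq_len(ny), dj + seq_len(nx)]
    res <- res & (img >= nb)
    strict <- strict | (img > nb)
  }
  res & strict
}

#' Detect diffraction-limited spots in one image frame
#'
#' Candidate spots are local maxima of a lightly smoothed image that exceed
#' the frame background by `threshold_sd` robust noise SDs (background and
#' noise estimated by sigma clipping, so crowded frames do not inflate the
#' threshold). Each candidate is refined to a sub-pixel position by
#' intensity centroiding over a `window x window` pixel region after
#' subtraction of the local background (median of the surrounding ring),
#' and its integrated intensity is the background-subtracted total over the
#' same window. The image is extended periodically before processing, so
#' spots near the frame edge are detected too (the synthetic movies use
#' periodic boundaries; for real data the edge rows are an approximation
#' either way). Coordinates are in um with the origin at the center of
#' pixel (0, 0).
#'
#' @param image numeric matrix of camera counts (one frame), or a
#'   [movie_stack()] together with `frame`.
#' @param pixel_size pixel size, um (taken from the stack if omitted).
#' @param params a [detect_params()].
#' @param frame 0-based frame index when `image` is a movie stack.
#' @return data.frame with columns `frame`, `x_um`, `y_um`,
#'   `intensity` (integrated counts above background), `background`
#'   (counts/pixel) and `saturated`.
#' @export
detect_spots <- function(image, pixel_size = NULL, params = detect_params(),
                         frame = 0L) {
  if (inherits(image, "movie_stack")) {
    if (is.null(pixel_size)) pixel_size <- attr(image, "pixel_size")
    image <- get_frame(image, frame)
  }
  stopifnot(is.matrix(image))
  if (is.null(pixel_size))
    stop("'pixel_size' is required when 'image' is a plain matrix",
         call. = FALSE)
  ny <- nrow(image); nx <- ncol(image)
  half <- (params$window - 1L) %/% 2L
  margin <- half + 2L  # room for the centroid window plus background ring
  # periodic extension so edge spots are detected with full windows
  ri <- c((ny - margin + 1L):ny, seq_len(ny), seq_len(margin))
  ci <- c((nx - margin + 1L):nx, seq_len(nx), seq_len(margin))
  image <- image[ri, ci]
  sm <- box_smooth3(image)
  bgstat <- clipped_background(sm)
  bg0 <- bgstat$mean
  noise <- bgstat$sd
  if (noise == 0) noise <- .Machine$double.eps
  cand <- local_maxima(sm) & (sm > bg0 + params$threshold_sd * noise)
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx)) {
    # keep each physical spot once: its peak inside the original frame
    keep <- idx[, 1L] > margin & idx[, 1L] <= ny + margin &
            idx[, 2L] > margin & idx[, 2L] <= nx + margin
    idx <- idx[keep, , drop = FALSE]
  }
  empty <- data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      background = numeric(0), saturated = logical(0))
  if (nrow(idx) == 0L) return(empty)
  # non-maximum suppression by min separation, brightest first
  ord <- order(sm[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  sep_px <- params$min_separation / pixel_size
  kept <- integer(0)
  for (r in seq_len(nrow(idx))) {
    if (length(kept)) {
      dd <- (idx[kept, 1L] - idx[r, 1L])^2 + (idx[kept, 2L] - idx[r, 2L])^2
      if (any(dd < sep_px^2)) next
    }
    kept <- c(kept, r)
  }
  idx <- idx[kept, , drop = FALSE]
  res <- lapply(seq_len(nrow(idx)), function(r) {
    i0 <- idx[r, 1L]; j0 <- idx[r, 2L]
    ring_half <- half + 2L
    block <- image[(i0 - ring_half):(i0 + ring_half),
                   (j0 - ring_half):(j0 + ring_half)]
    inner <- (ring_half - half + 1L):(ring_half + half + 1L)
    win <- block[inner, inner]
    ring <- block
    ring[inner, inner] <- NA
    bg <- median(ring, na.rm = TRUE)
    w <- pmax(win - bg, 0)
    tot <- sum(w)
    if (tot <= 0) return(NULL)
    rel <- (-half):half
    cy <- sum(rowSums(w) * rel) / tot  # row = y offset
    cx <- sum(colSums(w) * rel) / tot
    data.frame(frame = NA_integer_,
               x_um = (j0 - margin - 1L + cx) * pixel_size,
               y_um = (i0 - margin - 1L + cy) * pixel_size,
               intensity = sum(win - bg),
               background = bg,
               saturated = any(win >= 65535))
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  # map edge centroids back into the field
  res$x_um <- res$x_um %% (nx * pixel_size)
  res$y_um <- res$y_um %% (ny * pixel_size)
  res$frame <- as.integer(frame)
  if (any(res$saturated))
    warning("saturated pixels inside one or more spot windows; ",
            "spots flagged")
  rownames(res) <- NULL
  res
}

#' Detect spots in every frame of a movie
#'
#' @param movie a [movie_stack()].
#' @param params a [detect_params()].
#' @return data.frame of detections across all frames (see
#'   [detect_spots()]).
#' @export
detect_movie <- function(movie, params = detect_params()) {
  stopifnot(inherits(movie, "movie_stack"))
  nf <- dim(movie)[3L]
  px <- attr(movie, "pixel_size")
  out <- lapply(0:(nf - 1L), function(f)
    detect_spots(get_frame(movie, f), px, params, frame = f))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Measure the full width at half maximum of an isolated spot
#'
#' Fits a radially symmetric Gaussian `c + A * exp(-r^2 / (2 * sigma^2))`
#' to the pixel values around the brightest pixel and reports
#' `FWHM = 2.3548 * sigma`. A fitted width below twice the pixel size
#' cannot be a diffraction-limited image at this sampling and is flagged as
#' sub-resolution; non-convergence is flagged too.
#'
#' @param image matrix of counts containing one isolated spot.
#' @param pixel_size pixel size, um.
#' @param fit_half_width half width of the square fit region, pixels.
#' @return list with `fwhm_um`, `sigma_um`, `converged` and
#'   `sub_resolution`.
#' @export
measure_fwhm <- function(image, pixel_size, fit_half_width = 4L) {
  stopifnot(is.matrix(image))
  stop_if_not_scalar_number(pixel_size, "pixel_size", 0, allow_zero = FALSE)
  pk <- which(image == max(image), arr.ind = TRUE)[1L, ]
  h <- as.integer(fit_half_width)
  is <- max(1L, pk[1L] - h):min(nrow(image), pk[1L] + h)
  js <- max(1L, pk[2L] - h):min(ncol(image), pk[2L] + h)
  sub <- image[is, js]
  d <- expand.grid(i = is, j = js)
  d$z <- as.vector(sub)
  d$r2 <- ((d$i - pk[1L])^2 + (d$j - pk[2L])^2) * pixel_size^2
  fit <- tryCatch(
    nls(z ~ c0 + A * exp(-r2 / (2 * s^2)), data = d,
        start = list(c0 = min(d$z), A = max(d$z) - min(d$z),
                     s = fwhm_to_sigma(0.3))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(fwhm_um = NA_real_, sigma_um = NA_real_, converged = FALSE,
                sub_resolution = NA))
  s <- abs(unname(coef(fit)["s"]))
  fwhm <- sigma_to_fwhm(s)
  list(fwhm_um = fwhm, sigma_um = s, converged = TRUE,
       sub_resolution = fwhm < 2 * pixel_size)
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame nearest-neighbor linking: for each consecutive frame
#' pair, all candidate assignments within `max_disp` are resolved globally
#' by ascending distance (greedy), so no two spots in one frame join the
#' same track. Unmatched detections start new tracks; tracks that fail to
#' find a match within `max_gap` frames terminate. Tracks shorter than
#' `min_length` spots are discarded.
#'
#' @param spots data.frame of detections (from [detect_movie()]).
#' @param params a [link_params()].
#' @param frame_interval frame interval, s; needed when `max_disp` is to be
#'   derived automatically.
#' @return track table: `track_id`, `frame`, `x_um`, `y_um`, `intensity`,
#'   `background`.
#' @export
link_tracks <- function(spots, params = link_params(),
                        frame_interval = NULL) {
  if (is.null(spots) || nrow(spots) == 0L)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), background = numeric(0)))
  max_disp <- params$max_disp
  if (is.null(max_disp)) {
    if (is.null(frame_interval))
      stop("provide 'frame_interval' (or an explicit 'max_disp') so the ",
           "linking radius can be derived", call. = FALSE)
    max_disp <- 3 * sqrt(4 * params$d_max * frame_interval)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  by_frame <- split(seq_len(nrow(spots)), spots$frame)
  track_of <- integer(nrow(spots))          # track id per spot row
  n_tracks <- 0L
  # active set: track id -> row index of its last spot + last frame
  active_rows <- integer(0)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- by_frame[[as.character(f)]]
    # drop stale tracks
    if (length(active_rows)) {
      last_frames <- spots$frame[active_rows]
      active_rows <- active_rows[f - last_frames <= params$max_gap + 1L]
    }
    assigned <- rep(FALSE, length(rows))
    if (length(active_rows)) {
      dx <- outer(spots$x_um[active_rows], spots$x_um[rows], "-")
      dy <- outer(spots$y_um[active_rows], spots$y_um[rows], "-")
      dmat <- sqrt(dx * dx + dy * dy)
      cand <- which(dmat <= max_disp, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        used_active <- rep(FALSE, length(active_rows))
        for (r in seq_len(nrow(cand))) {
          a <- cand[r, 1L]; b <- cand[r, 2L]
          if (used_active[a] || assigned[b]) next
          used_active[a] <- TRUE
          assigned[b] <- TRUE
          track_of[rows[b]] <- track_of[active_rows[a]]
          active_rows[a] <- rows[b]
        }
      }
    }
    new <- rows[!assigned]
    if (length(new)) {
      track_of[new] <- n_tracks + seq_along(new)
      n_tracks <- n_tracks + length(new)
      active_rows <- c(active_rows, new)
    }
  }
  out <- data.frame(track_id = track_of, frame = spots$frame,
                    x_um = spots$x_um, y_um = spots$y_um,
                    intensity = spots$intensity,
                    background = spots$background)
  len <- table(out$track_id)
  keep <- names(len)[len >= params$min_length]
  out <- out[out$track_id %in% as.integer(keep), , drop = FALSE]
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  # renumber consecutively
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out
}
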