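#' Write a movie stack as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pixel counts are stored as 16-bit unsigned grayscale. The physical
#' calibration (pixel size, frame interval) plus any extra metadata are
#' written to `<path>.json` so a movie can be re-read without guessing
#' units.
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path.
#' @param metadata named list of extra metadata (e.g. the generating
#'   config and seed) merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, metadata = list()) {
  stopifnot(inherits(movie, "movie_stack"))
  nf <- dim(movie)[3L]
  pages <- lapply(seq_len(nf), function(f) movie[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- c(list(pixel_size_um = attr(movie, "pixel_size"),
                    frame_interval_s = attr(movie, "frame_interval"),
                    n_frames = nf),
               metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibrated movie stack from TIFF
#'
#' Reads a multi-page grayscale TIFF plus its JSON sidecar
#' (`<path>.json`). If the sidecar is missing, `pixel_size` and
#' `frame_interval` must be supplied explicitly; units are never silently
#' assumed. RGB/multi-channel TIFFs are rejected.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval calibration overrides (um, s); used
#'   when the sidecar is absent.
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("multi-channel (RGB) TIFF is not a grayscale movie stack",
         call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
  } else if (!is.null(pixel_size) && !is.null(frame_interval)) {
    message("no sidecar found for ", path,
            "; using the calibration supplied by the caller")
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("missing calibration: supply 'pixel_size' and 'frame_interval' ",
         "or provide the JSON sidecar", call. = FALSE)
  counts <- array(0L, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]),
                              length(pages)))
  for (f in seq_along(pages))
    counts[, , f] <- as.integer(round(pages[[f]]))
  movie_stack(counts, pixel_size, frame_interval)
}

TRACK_COLUMNS <- c("track_id", "frame", "x_um", "y_um", "intensity",
                   "background")

validate_tracks <- function(tracks, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("track table", where, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !is.finite(tracks$x_um) | !is.finite(tracks$y_um) |
    !is.finite(tracks$frame)
  if (any(bad))
    stop("non-finite values in track table", where, " at row(s) ",
         paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
  by_track <- split(seq_len(nrow(tracks)), tracks$track_id)
  for (rows in by_track) {
    f <- tracks$frame[rows]
    if (is.unsorted(f, strictly = TRUE)) {
      row <- rows[which(diff(f) <= 0)[1L] + 1L]
      stop("frames not strictly increasing within track ",
           tracks$track_id[rows[1L]], where, " (row ", row, ")",
           call. = FALSE)
    }
  }
  invisible(tracks)
}

#' Read and write track tables
#'
#' Tracks are stored as plain CSV with columns `track_id`, `frame`,
#' `x_um`, `y_um`, `intensity`, `background` (units in the column names).
#' Reading validates the schema and that frames increase strictly within
#' each track; `write_tracks` followed by `read_tracks` is the identity.
#'
#' @param tracks track table (from [link_tracks()]).
#' @param path CSV path.
#' @return `read_tracks` returns the validated track table;
#'   `write_tracks` returns `path` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  for (col in TRACK_COLUMNS)
    if (!col %in% names(tracks)) tracks[[col]] <- NA_real_
  write.csv(tracks[TRACK_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tracks <- tryCatch(read.csv(path), error = function(e)
    stop("cannot parse track CSV ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (nrow(tracks) == 0L) {
    miss <- setdiff(TRACK_COLUMNS, names(tracks))
    if (length(miss))
      stop("track CSV ", path, " lacks column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    return(tracks)
  }
  validate_tracks(tracks, file = path)
  tracks
}
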