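#' Score photobleaching trajectory types for all tracks of a movie
#'
#' Runs the stoichiometry chain on every track: intensity-trace extraction
#' (extended past the track end so the final drop to background is
#' visible), 3-point median smoothing, derivative-based step detection,
#' and deterministic type classification against a single-fluorophore unit
#' intensity. When `unit_intensity` is `NULL` it is calibrated as the mode
#' of the per-spot mean counts/pixel over all tracked spots
#' ([intensity_histogram()]).
#'
#' @param movie a [movie_stack()].
#' @param tracks track table.
#' @param unit_intensity single-fluorophore trace intensity
#'   (counts/pixel), or `NULL` to calibrate from the data.
#' @param window intensity window side, pixels.
#' @param threshold_sd step-detection threshold.
#' @param extend_frames frames appended past the track end.
#' @return list with `types` (data.frame: `track_id`, `type`),
#'   `fractions` (named proportions over classified tracks),
#'   `unit_intensity` and `n_tracks`.
#' @export
score_trajectory_types <- function(movie, tracks, unit_intensity = NULL,
                                   window = 5L, threshold_sd = 4,
                                   extend_frames = 8L) {
  stopifnot(inherits(movie, "movie_stack"))
  ids <- unique(tracks$track_id)
  if (!length(ids)) stop("no tracks to score", call. = FALSE)
  traces <- lapply(ids, function(id)
    extract_intensity_trace(movie, tracks[tracks$track_id == id, ,
                                          drop = FALSE],
                            window = window, extend_frames = extend_frames))
  if (is.null(unit_intensity)) {
    pooled <- unlist(lapply(traces, function(tr)
      tr$intensity[tr$tracked & !tr$flagged]))
    unit_intensity <- intensity_histogram(pooled)$mode
  }
  types <- vapply(traces, function(tr) {
    x <- tr$intensity[!tr$flagged]
    if (length(x) < 3L) return("unclassified")
    fit <- detect_steps(median_smooth(x), window = window,
                        threshold_sd = threshold_sd)
    classify_trajectory(fit, unit_intensity)
  }, character(1))
  classified <- types[types != "unclassified"]
  fractions <- if (length(classified))
    prop.table(table(factor(classified,
                            levels = c("type1", "type2", "type3",
                                       "dimer_other", "higher_oligomer"))))
  else NULL
  list(types = data.frame(track_id = ids, type = types),
       fractions = fractions, unit_intensity = unit_intensity,
       n_tracks = length(ids))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full simulate - detect - track - analyze pipeline
#'
#' Chains movie simulation (or reading), spot detection, track linking,
#' MSD-based diffusion estimation with motion classification, density
#' estimation by spot counting, and photobleaching-type scoring into one
#' report. Every stochastic stage derives from the single seed recorded in
#' the config, so two runs with the same configuration produce identical
#' reports.
#'
#' @param config a [movie_config()] describing the movie to simulate, or a
#'   path to a TIFF movie written by [write_movie()].
#' @param detect a [detect_params()].
#' @param link a [link_params()].
#' @param n_fit_points lags used in the diffusion fit.
#' @param max_lag largest MSD lag, frames.
#' @param score_types whether to run the stoichiometry stage.
#' @return list of class `"tirf_report"` with elements `provenance`
#'   (package version, seed, config), `tracking` (spot/track counts),
#'   `diffusion` (`d_lat`, `se`, `intercept`, `motion_class`, `alpha`),
#'   `density` (`rho`, `se`, `flagged`) and `stoichiometry` (type
#'   fractions and unit intensity), plus the `tracks` table.
#' @export
pipeline_run <- function(config, detect = detect_params(),
                         link = link_params(), n_fit_points = 4L,
                         max_lag = 8L, score_types = TRUE) {
  if (is.character(config)) {
    movie <- run_stage("read_movie", read_movie(config))
    cfg <- NULL
    area <- prod(dim(movie)[1:2]) * attr(movie, "pixel_size")^2
  } else {
    stopifnot(inherits(config, "movie_config"))
    cfg <- config
    sim <- run_stage("simulate", simulate_movie(cfg))
    movie <- sim$movie
    area <- cfg$field_width * cfg$field_height
  }
  dt <- attr(movie, "frame_interval")
  spots <- run_stage("detect", detect_movie(movie, detect))
  tracks <- run_stage("link",
                      link_tracks(spots, link, frame_interval = dt))
  if (nrow(tracks) == 0L)
    stop("pipeline stage 'link' failed: no tracks passed the length filter",
         call. = FALSE)
  curve <- run_stage("msd", msd_curve(tracks, dt,
                                      max_lag = max_lag))
  est <- run_stage("fit_dlat", fit_dlat(curve, n_fit_points))
  motion <- if (nrow(curve) >= 4L) classify_motion(curve)
            else list(motion_class = NA_character_, alpha = NA_real_)
  # count over the first frames only, before photobleaching thins the field
  dens <- run_stage("density", count_density(spots, area, n_early = 10L))
  stoich <- if (score_types)
    run_stage("stoichiometry", score_trajectory_types(movie, tracks))
  else NULL
  report <- list(
    provenance = list(package = "tirftrack",
                      version = as.character(packageVersion("tirftrack")),
                      seed = if (!is.null(cfg)) cfg$rng_seed else NA,
                      config = if (!is.null(cfg)) unclass(cfg) else config),
    tracking = list(n_spots = nrow(spots),
                    n_tracks = length(unique(tracks$track_id))),
    diffusion = list(d_lat = est$d_lat, se = est$se,
                     intercept = est$intercept,
                     motion_class = motion$motion_class,
                     alpha = motion$alpha),
    density = list(rho = dens$rho, se = dens$se, flagged = dens$flagged),
    stoichiometry = if (!is.null(stoich))
      list(fractions = as.list(stoich$fractions),
           unit_intensity = stoich$unit_intensity,
           n_tracks = stoich$n_tracks)
    else NULL,
    tracks = tracks)
  class(report) <- "tirf_report"
  report
}

#' @export
print.tirf_report <- function(x, ...) {
  cat("TIRF pipeline report\n")
  cat(sprintf("  %d spots -> %d tracks\n", x$tracking$n_spots,
              x$tracking$n_tracks))
  cat(sprintf("  D_lat = %.4g +/- %.2g um^2/s (%s)\n", x$diffusion$d_lat,
              x$diffusion$se, x$diffusion$motion_class))
  cat(sprintf("  rho = %.3g +/- %.2g um^-2%s\n", x$density$rho,
              x$density$se,
              if (isTRUE(x$density$flagged)) " (flagged)" else ""))
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report a [pipeline_run()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$tracks <- NULL  # tables go to CSV via write_tracks, not into JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
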