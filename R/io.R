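# Track/curve table I/O and the end-to-end pipeline driver.

track_csv_cols <- c(
  "track_id", "frame", "x_px", "y_px", "x_um", "y_um",
  "intensity", "quality", "precision_nm"
)

#' Write tracks to CSV
#'
#' Columns: track_id, frame, x_px, y_px, x_um, y_um, intensity, quality,
#' precision_nm. Positions are stored in both px and um so no downstream
#' tool has to guess the pixel size. Missing columns are written as NA.
#'
#' @param tracks An `spt_tracks` tibble (a localization table without
#'   `track_id` is also accepted for the `detect` stage).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- tibble::as_tibble(tracks)
  for (col in track_csv_cols) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  readr::write_csv(df[track_csv_cols], path)
  invisible(path)
}

#' Read tracks from CSV
#'
#' @param path CSV written by [write_tracks()] (header checked).
#' @param pixel_size,frame_interval Calibration to attach.
#' @return An `spt_tracks` tibble.
#' @export
read_tracks <- function(path, pixel_size = 0.1, frame_interval = 0.03) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(c("track_id", "frame", "x_um", "y_um"), hdr)
  if (length(missing) > 0) {
    stop(
      "malformed track table ", path, ": missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  new_spt_tracks(df, pixel_size, frame_interval)
}

#' Write / read an MSD curve as CSV
#'
#' @param curve An `spt_msd` tibble.
#' @param path CSV path.
#' @return `path` (write) or an `spt_msd` tibble (read).
#' @export
write_msd <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve), path)
  invisible(path)
}

#' @rdname write_msd
#' @export
read_msd <- function(path) {
  if (!file.exists(path)) stop("MSD file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("lag", "msd") %in% names(df))) {
    stop("malformed MSD table: needs 'lag' and 'msd' columns", call. = FALSE)
  }
  new_spt_msd(df, source = "file")
}

#' Run the full analysis pipeline on a movie
#'
#' Localize every frame, link into tracks, filter by spot count, compute
#' per-track and ensemble MSD, fit per-track and ensemble diffusion, and
#' compute the mobile-to-immobile ratio. When `out_dir` is given, writes
#' `localizations.csv`, `tracks.csv`, `msd_ensemble.csv`,
#' `diffusion.csv` and `report.csv` there.
#'
#' @param movie An [spt_movie()] or a path to a multi-page TIFF.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param verbose Print stage progress.
#' @return List of class `spt_pipeline`: `localizations`, `tracks`,
#'   `tracks_filtered`, `per_track_msd`, `ensemble` (spt_msd),
#'   `ensemble_fit` (spt_dfit), `diffusion` (per-track), `mobility`
#'   (ratio tibble), `log` (counts and thresholds).
#' @export
run_pipeline <- function(movie, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(movie)) {
    movie <- read_movie(movie,
      pixel_size = config$pixel_size,
      frame_interval = config$frame_interval
    )
  }
  stopifnot(inherits(movie, "spt_movie"), inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)

  say("localizing ", dim(movie)[3], " frames")
  locs <- localize_movie(movie, config$detection)
  say("  ", nrow(locs), " localizations (threshold ",
    signif(attr(locs, "quality_threshold"), 4), ", ",
    attr(locs, "n_dropped"), " fits dropped)")

  say("linking")
  tracks <- link_movie(locs, config$linking,
    pixel_size = config$pixel_size, frame_interval = config$frame_interval
  )
  filtered <- filter_tracks(tracks, config$min_spots, config$max_spots)
  say(
    "  ", length(unique(tracks$track_id)), " tracks, ",
    length(unique(filtered$track_id)), " kept after length filter"
  )

  per_track <- track_msds(filtered,
    frame_interval = config$frame_interval,
    n_max = config$msd_n_max
  )
  ens <- ensemble_msd(per_track, n_max = config$msd_n_max)
  ens_fit <- fit_diffusion(ens)
  dcoef <- track_diffusion(filtered, frame_interval = config$frame_interval)
  mob <- mobility_ratio(dcoef)

  log <- list(
    n_localizations = nrow(locs),
    quality_threshold = attr(locs, "quality_threshold"),
    n_dropped_fits = attr(locs, "n_dropped"),
    n_tracks = length(unique(tracks$track_id)),
    n_tracks_kept = length(unique(filtered$track_id)),
    n_removed_short = attr(filtered, "n_removed_short"),
    n_removed_long = attr(filtered, "n_removed_long"),
    n_negative_D = mob$n_excluded
  )

  result <- structure(
    list(
      localizations = locs, tracks = tracks, tracks_filtered = filtered,
      per_track_msd = per_track, ensemble = ens, ensemble_fit = ens_fit,
      diffusion = dcoef, mobility = mob, config = config, log = log
    ),
    class = "spt_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(locs, file.path(out_dir, "localizations.csv"))
    write_tracks(filtered, file.path(out_dir, "tracks.csv"))
    write_msd(ens, file.path(out_dir, "msd_ensemble.csv"))
    readr::write_csv(dcoef, file.path(out_dir, "diffusion.csv"))
    report <- tibble::tibble(
      n_localizations = log$n_localizations,
      n_tracks = log$n_tracks,
      n_tracks_kept = log$n_tracks_kept,
      ensemble_D = ens_fit$D,
      ensemble_alpha = ens_fit$alpha,
      mobile_fraction = mob$mobile_fraction,
      immobile_fraction = mob$immobile_fraction,
      mobile_immobile_ratio = mob$ratio
    )
    readr::write_csv(report, file.path(out_dir, "report.csv"))
  }
  result
}

#' @export
print.spt_pipeline <- function(x, ...) {
  cat("sptPALM pipeline result\n",
    "  localizations: ", x$log$n_localizations, "\n",
    "  tracks: ", x$log$n_tracks, " (", x$log$n_tracks_kept,
    " with ", x$config$min_spots, "-", x$config$max_spots, " spots)\n",
    "  ensemble D: ", signif(x$ensemble_fit$D, 4), " um^2/s, alpha ",
    signif(x$ensemble_fit$alpha, 4), " um^2\n",
    "  mobile:immobile = ", signif(x$mobility$ratio, 4), "\n",
    sep = ""
  )
  invisible(x)
}
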