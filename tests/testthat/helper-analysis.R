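# Shared analysis shorthands for the end-to-end tests.

curve_value_at <- function(curve, lag) {
  curve$msd[which.min(abs(curve$lag - lag))]
}

# ground truth -> filtered observable tracks -> ensemble MSD curve
truth_ensemble <- function(truth, sigma_loc = 0.018, n_max = 10) {
  tracks <- filter_tracks(truth_tracks(truth, sigma_loc = sigma_loc))
  ensemble_msd(
    track_msds(tracks, truth$config$frame_interval, n_max),
    n_max
  )
}

# Detect + refine every frame of a rendered movie of static emitters and
# score against the known positions: recall, precision, localization RMSE.
detection_metrics <- function(movie, positions, cfg, match_radius_px = 1.5) {
  sigma_px <- psf_sigma_px(cfg)
  clean_cfg <- cfg
  clean_cfg$background <- 0
  clean_cfg$read_noise <- 0
  clean_cfg$n_frames <- 1L
  centre <- tibble::tibble(
    x_um = (cfg$image_size[2] - 1) * cfg$pixel_size / 2,
    y_um = (cfg$image_size[1] - 1) * cfg$pixel_size / 2
  )
  clean <- max_projection(
    render_movie(static_spot_truth(centre, clean_cfg), clean_cfg, seed = 1)
  )
  thr <- 0.25 * max(log_filter(clean, sigma_px))
  dcfg <- detection_config(log_sigma = sigma_px, quality_threshold = thr)

  tp <- 0
  fp <- 0
  fn <- 0
  errs <- c()
  for (t in seq_len(dim(movie)[3])) {
    frame <- unclass(movie)[, , t]
    locs <- refine_subpixel(
      frame, detect_spots(frame, dcfg), dcfg, cfg$pixel_size
    )
    if (nrow(locs) == 0) {
      fn <- fn + nrow(positions)
      next
    }
    d <- sqrt(
      outer(locs$x_px, positions$x_um / cfg$pixel_size, "-")^2 +
        outer(locs$y_px, positions$y_um / cfg$pixel_size, "-")^2
    )
    match <- apply(d, 1, which.min)
    dist <- d[cbind(seq_len(nrow(locs)), match)]
    hit <- dist < match_radius_px
    n_matched <- length(unique(match[hit]))
    tp <- tp + n_matched
    fp <- fp + sum(!hit) + (sum(hit) - n_matched)
    fn <- fn + nrow(positions) - n_matched
    errs <- c(errs, dist[hit])
  }
  list(
    recall = tp / (tp + fn),
    precision = tp / (tp + fp),
    rmse_px = sqrt(mean(errs^2))
  )
}
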