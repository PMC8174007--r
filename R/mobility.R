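# Track filtering, mean squared displacement, four-point diffusion fits,
# and the mobile-to-immobile ratio.

#' Filter tracks by spot count
#'
#' Keeps tracks with between `min_spots` and `max_spots` localizations
#' (defaults 6 and 1000, the analysis bounds). Removal counts are recorded
#' in the `n_removed_short` / `n_removed_long` attributes.
#'
#' @param tracks An `spt_tracks` tibble (needs `track_id`).
#' @param min_spots,max_spots Inclusive bounds.
#' @return Filtered tracks of the same class.
#' @export
filter_tracks <- function(tracks, min_spots = 6L, max_spots = 1000L) {
  stopifnot("track_id" %in% names(tracks), min_spots >= 1,
    max_spots >= min_spots)
  len <- dplyr::count(tracks, .data$track_id, name = "n_spots")
  keep <- len$track_id[len$n_spots >= min_spots & len$n_spots <= max_spots]
  out <- dplyr::filter(tracks, .data$track_id %in% keep)
  attr(out, "pixel_size") <- attr(tracks, "pixel_size")
  attr(out, "frame_interval") <- attr(tracks, "frame_interval")
  attr(out, "n_removed_short") <- sum(len$n_spots < min_spots)
  attr(out, "n_removed_long") <- sum(len$n_spots > max_spots)
  class(out) <- class(tracks)
  out
}

#' Mean squared displacement of one track
#'
#' For each lag n = 1..n_max, averages the squared displacement over all
#' N - n ordered pairs (i, i + n):
#' MSD(n dt) = sum_i [x(i+n) - x(i)]^2 + [y(i+n) - y(i)]^2 / (N - n).
#'
#' @param track Tibble with `x_um`, `y_um` ordered by frame (consecutive
#'   frames, as produced by the linker).
#' @param frame_interval Frame interval in seconds.
#' @param n_max Number of lags; must be smaller than the number of spots.
#' @return An `spt_msd` tibble: `lag` (s), `msd` (um^2), `n_pairs`.
#' @examples
#' trk <- tibble::tibble(x_um = c(0, 1, 2), y_um = c(0, 0, 0))
#' compute_msd(trk, frame_interval = 0.03, n_max = 2)
#' @export
compute_msd <- function(track, frame_interval, n_max) {
  stopifnot(
    all(c("x_um", "y_um") %in% names(track)),
    frame_interval > 0, n_max >= 1
  )
  n <- nrow(track)
  if (n_max >= n) {
    stop("n_max must be smaller than the number of spots in the track",
      call. = FALSE
    )
  }
  x <- track$x_um
  y <- track$y_um
  msd <- vapply(seq_len(n_max), function(lag) {
    dx <- x[(lag + 1):n] - x[seq_len(n - lag)]
    dy <- y[(lag + 1):n] - y[seq_len(n - lag)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  new_spt_msd(
    tibble::tibble(
      lag = frame_interval * seq_len(n_max),
      msd = msd,
      n_pairs = n - seq_len(n_max)
    ),
    source = "track"
  )
}

#' Per-track MSD curves for a set of tracks
#'
#' @param tracks An `spt_tracks` tibble.
#' @param frame_interval Frame interval (s); default from the tracks
#'   attribute.
#' @param n_max Maximum lag count; tracks contribute lags up to
#'   `min(n_max, n_spots - 1)`.
#' @return Tibble with `track_id`, `lag`, `msd`, `n_pairs`.
#' @export
track_msds <- function(tracks, frame_interval = NULL, n_max = 10L) {
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 0.03
  split(tibble::as_tibble(tracks), tracks$track_id) |>
    purrr::map(function(trk) {
      k <- min(n_max, nrow(trk) - 1L)
      if (k < 1) {
        return(NULL)
      }
      curve <- compute_msd(trk, frame_interval, k)
      dplyr::bind_cols(tibble::tibble(track_id = trk$track_id[1]), curve)
    }) |>
    dplyr::bind_rows()
}

#' Ensemble MSD across tracks
#'
#' Unweighted mean and sample SD across tracks at each lag; tracks shorter
#' than a lag simply do not contribute there. Pair-count weighting is
#' available as an option.
#'
#' @param per_track Tibble from [track_msds()] (`track_id`, `lag`, `msd`,
#'   `n_pairs`).
#' @param n_max Keep at most this many lags.
#' @param weight_by_pairs If `TRUE`, the mean at each lag weights tracks
#'   by their pair count (default `FALSE`: every track counts equally).
#' @return An `spt_msd` tibble: `lag`, `msd`, `sd`, `n_tracks`, `n_pairs`.
#' @export
ensemble_msd <- function(per_track, n_max = 10L, weight_by_pairs = FALSE) {
  stopifnot(all(c("lag", "msd") %in% names(per_track)))
  if (nrow(per_track) == 0) {
    stop("no per-track MSD values to average", call. = FALSE)
  }
  keep_lags <- sort(unique(per_track$lag))[seq_len(min(
    n_max,
    length(unique(per_track$lag))
  ))]
  out <- per_track |>
    dplyr::filter(.data$lag %in% keep_lags) |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(
      value = if (weight_by_pairs) {
        sum(.data$msd * .data$n_pairs) / sum(.data$n_pairs)
      } else {
        mean(.data$msd)
      },
      sd = sd(.data$msd),
      n_tracks = dplyr::n(),
      n_pairs = sum(.data$n_pairs),
      .groups = "drop"
    ) |>
    dplyr::rename(msd = "value") |>
    dplyr::arrange(.data$lag)
  new_spt_msd(out, source = "ensemble")
}

new_spt_msd <- function(df, source) {
  structure(
    tibble::as_tibble(df),
    source = source,
    class = c("spt_msd", class(tibble::tibble()))
  )
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of MSD(tau) = alpha + 4 D tau over the first
#' four lag points; D is slope/4 and alpha, the intercept, absorbs
#' localization error and finite camera exposure.
#'
#' @param curve An `spt_msd` tibble (or any tibble with `lag` and `msd`)
#'   with at least four lags.
#' @return An object of class `spt_dfit` with elements `D` (um^2/s),
#'   `alpha` (um^2), `r_squared`, `n_points`, and the underlying `lm` fit.
#' @examples
#' curve <- tibble::tibble(lag = 0.03 * 1:4, msd = 0.01 + 4 * 0.1 * 0.03 * 1:4)
#' fit_diffusion(curve)
#' @export
fit_diffusion <- function(curve) {
  stopifnot(all(c("lag", "msd") %in% names(curve)))
  if (nrow(curve) < 4) {
    stop("diffusion fit needs at least four lag points", call. = FALSE)
  }
  pts <- dplyr::arrange(tibble::as_tibble(curve), .data$lag)[1:4, ]
  fit <- lm(msd ~ lag, data = pts)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((pts$msd - mean(pts$msd))^2)
  structure(
    list(
      D = unname(coef(fit)[2]) / 4,
      alpha = unname(coef(fit)[1]),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      n_points = 4L,
      fit = fit
    ),
    class = "spt_dfit"
  )
}

#' @export
print.spt_dfit <- function(x, ...) {
  cat(
    "Diffusion fit (first 4 lags): D = ", signif(x$D, 4),
    " um^2/s, alpha = ", signif(x$alpha, 4), " um^2, R^2 = ",
    signif(x$r_squared, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-track diffusion coefficients
#'
#' Four-point diffusion fit on each track's own MSD curve. Tracks need at
#' least five spots (four lags); with the standard minimum of six spots
#' every retained track qualifies.
#'
#' @param tracks An `spt_tracks` tibble (ideally already through
#'   [filter_tracks()]).
#' @param frame_interval Frame interval (s); default from attributes.
#' @return Tibble: `track_id`, `n_spots`, `D`, `alpha`, `r_squared`.
#' @export
track_diffusion <- function(tracks, frame_interval = NULL) {
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 0.03
  split(tibble::as_tibble(tracks), tracks$track_id) |>
    purrr::map(function(trk) {
      if (nrow(trk) < 5) {
        return(NULL)
      }
      curve <- compute_msd(trk, frame_interval, min(4L, nrow(trk) - 1L))
      f <- fit_diffusion(curve)
      tibble::tibble(
        track_id = trk$track_id[1], n_spots = nrow(trk),
        D = f$D, alpha = f$alpha, r_squared = f$r_squared
      )
    }) |>
    dplyr::bind_rows()
}

#' Mobile-to-immobile ratio
#'
#' Classifies each track's diffusion coefficient as mobile
#' (log10(D) > threshold) or immobile (log10(D) <= threshold) and returns
#' the fraction of each plus their ratio. The default threshold of -1.6
#' corresponds to D = 0.025 um^2/s (\eqn{10^{-1.6}}). Tracks with D <= 0
#' (pure-noise fits) are excluded and counted. If the immobile fraction is
#' zero the ratio is undefined and flagged rather than returned as
#' infinity.
#'
#' @param D Numeric vector of per-track diffusion coefficients (um^2/s),
#'   or the tibble from [track_diffusion()].
#' @param log10_threshold Mobility cutoff on the log10 scale (default
#'   -1.6).
#' @return One-row tibble: `n_included`, `n_excluded`, `mobile_fraction`,
#'   `immobile_fraction`, `ratio`, `ratio_defined`.
#' @examples
#' mobility_ratio(c(0.1, 0.01, 0.001))
#' @export
mobility_ratio <- function(D, log10_threshold = -1.6) {
  if (is.data.frame(D)) D <- D$D
  n_excluded <- sum(D <= 0 | !is.finite(D))
  D <- D[D > 0 & is.finite(D)]
  if (length(D) == 0) {
    stop("no tracks with positive diffusion coefficient", call. = FALSE)
  }
  mobile <- mean(log10(D) > log10_threshold)
  immobile <- 1 - mobile
  # a one-sided split (every track on the same side of the threshold) has
  # no meaningful ratio: flagged rather than returned as 0 or infinity
  defined <- immobile > 0 && mobile > 0
  tibble::tibble(
    n_included = length(D),
    n_excluded = n_excluded,
    mobile_fraction = mobile,
    immobile_fraction = immobile,
    ratio = if (defined) mobile / immobile else NA_real_,
    ratio_defined = defined
  )
}
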