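#' Simulation configuration
#'
#' Collects every knob of the synthetic sptPALM movie generator. Defaults
#' emulate the acquisition this pipeline targets: a 512x512 EMCCD at
#' 0.1 um/px (16-um camera pixels behind a 100x objective and 1.6x lens),
#' 30-ms continuous exposure, sparse photoconverted mEos2-like emitters
#' (about ten visible per frame, modal on-segment eight frames) diffusing in
#' 2D with a mixture of mobile and immobile populations.
#'
#' Photophysics is a four-state chain per molecule:
#' unconverted -> on <-> dark (blink) -> bleached (absorbing), with
#' independent per-frame transition probabilities. A molecule is observable
#' only while "on"; because the tracker does no gap closing, a blink ends
#' one track and may start another.
#'
#' @param n_frames Number of frames to simulate.
#' @param frame_interval Frame interval in seconds (default 0.03).
#' @param image_size Integer vector `c(height, width)` in pixels.
#' @param pixel_size Pixel size in micrometres per pixel (default 0.1).
#' @param D_populations Data frame or tibble with columns `D` (um^2/s) and
#'   `fraction` (summing to 1): the diffusion mixture. The default is 80%
#'   mobile at 0.1 um^2/s and 20% immobile at 0.001 um^2/s.
#' @param n_molecules Size of the unconverted molecule pool.
#' @param conversion_rate Per-frame probability that an unconverted molecule
#'   photoconverts (switches on).
#' @param bleach_rate Per-frame probability that an "on" molecule bleaches
#'   irreversibly.
#' @param blink_off_rate Per-frame probability that an "on" molecule enters
#'   a reversible dark state.
#' @param blink_on_rate Per-frame probability that a dark molecule returns
#'   to "on".
#' @param psf_half_width PSF half width (FWHM/2) in nanometres; default
#'   127.9 nm, i.e. a Gaussian sigma of about 108.6 nm.
#' @param photons_per_frame Mean photons emitted per "on" molecule per frame.
#' @param background Mean background level, photons per pixel per frame.
#' @param read_noise Gaussian read noise, photons RMS.
#' @param em_gain Camera gain applied after shot noise (digital numbers per
#'   photon).
#' @param drift_velocity Length-2 numeric, stage drift in px/frame (x, y);
#'   applied at render time via [inject_drift()].
#' @param confinement_radius Half-width (um) of a reflecting square box
#'   centred on each molecule's initial position, emulating membrane
#'   compartments; `Inf` (default) disables confinement.
#' @param site_positions Optional tibble (`x_um`, `y_um`) of compartment
#'   sites; molecules then start near a random site and, with a finite
#'   `confinement_radius`, stay confined to it. Shared sites give repeated
#'   recordings of the same field a common max-projection structure.
#' @param seed Integer seed; every stochastic stage derives from it.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_trajectories()], [render_movie()]
#' @export
sim_config <- function(n_frames = 500,
                       frame_interval = 0.03,
                       image_size = c(512L, 512L),
                       pixel_size = 0.1,
                       D_populations = tibble::tibble(
                         D = c(0.1, 0.001),
                         fraction = c(0.8, 0.2)
                       ),
                       n_molecules = 20000L,
                       conversion_rate = 5e-5,
                       bleach_rate = 0.10,
                       blink_off_rate = 0.025,
                       blink_on_rate = 0.20,
                       psf_half_width = 127.9,
                       photons_per_frame = 100,
                       background = 6,
                       read_noise = 1,
                       em_gain = 1,
                       drift_velocity = c(0, 0),
                       confinement_radius = Inf,
                       site_positions = NULL,
                       seed = 1L) {
  D_populations <- tibble::as_tibble(D_populations)
  stopifnot(
    n_frames >= 1, frame_interval > 0, pixel_size > 0,
    length(image_size) == 2, all(image_size >= 8),
    all(c("D", "fraction") %in% names(D_populations)),
    all(D_populations$D >= 0),
    n_molecules >= 1, photons_per_frame >= 0, background >= 0,
    read_noise >= 0, em_gain > 0, psf_half_width > 0,
    length(drift_velocity) == 2, all(is.finite(drift_velocity)),
    confinement_radius > 0
  )
  rates <- c(conversion_rate, bleach_rate, blink_off_rate, blink_on_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all photophysics rates must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(D_populations$fraction) - 1) > 1e-8) {
    stop("D_populations fractions must sum to 1", call. = FALSE)
  }
  structure(
    list(
      n_frames = as.integer(n_frames),
      frame_interval = frame_interval,
      image_size = as.integer(image_size),
      pixel_size = pixel_size,
      D_populations = D_populations,
      n_molecules = as.integer(n_molecules),
      conversion_rate = conversion_rate,
      bleach_rate = bleach_rate,
      blink_off_rate = blink_off_rate,
      blink_on_rate = blink_on_rate,
      psf_half_width = psf_half_width,
      photons_per_frame = photons_per_frame,
      background = background,
      read_noise = read_noise,
      em_gain = em_gain,
      drift_velocity = as.numeric(drift_velocity),
      confinement_radius = confinement_radius,
      site_positions = site_positions,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Gaussian sigma of the configured PSF, in pixels
#'
#' The configured half width is FWHM/2, so sigma = half_width /
#' sqrt(2 log 2).
#' @param config A [sim_config()].
#' @return Sigma in pixels.
#' @export
psf_sigma_px <- function(config) {
  (config$psf_half_width / 1000) / sqrt(2 * log(2)) / config$pixel_size
}

#' Spot detection configuration
#'
#' @param log_sigma Scale of the Laplacian-of-Gaussian detector in pixels
#'   (the Gaussian sigma; match it to the PSF sigma, about 1.1 px at
#'   0.1 um/px for a 127.9-nm half-width PSF).
#' @param quality_threshold Minimum LoG response at a local maximum for it
#'   to count as a spot. The original analysis set this manually per
#'   recording; `NULL` selects it automatically as an upper quantile of the
#'   response of a reference frame (see `auto_quantile`).
#' @param auto_quantile Quantile used for the automatic threshold.
#' @param use_median_filter Apply a 3x3 median prefilter to the raw frame
#'   before LoG filtering (default `TRUE`).
#' @param refine_window Side of the square window (px, odd, >= 5) used for
#'   subpixel Gaussian refinement.
#'
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(log_sigma = 1.1,
                             quality_threshold = NULL,
                             auto_quantile = 0.9995,
                             use_median_filter = TRUE,
                             refine_window = 7L) {
  stopifnot(
    log_sigma > 0,
    is.null(quality_threshold) || is.finite(quality_threshold),
    auto_quantile > 0, auto_quantile < 1,
    is.logical(use_median_filter)
  )
  refine_window <- as.integer(refine_window)
  if (refine_window < 5L || refine_window %% 2L == 0L) {
    stop("refine_window must be odd and >= 5", call. = FALSE)
  }
  structure(
    list(
      log_sigma = log_sigma,
      quality_threshold = quality_threshold,
      auto_quantile = auto_quantile,
      use_median_filter = use_median_filter,
      refine_window = refine_window
    ),
    class = "detection_config"
  )
}

#' Frame-to-frame linking configuration
#'
#' @param max_linking_distance Maximum allowed displacement (um) between a
#'   detection in frame t and its continuation in frame t+1; larger
#'   distances are impossible links. Default 0.3 um (about 3 px), chosen so
#'   a molecule diffusing at 0.1 um^2/s exceeds it in under 1% of 30-ms
#'   steps.
#' @param alternative_cost_factor Birth/death alternative cost as a multiple
#'   of `max_linking_distance^2`; must exceed 1 so that any admissible link
#'   is preferred over a death plus a birth.
#'
#' @return A list of class `linking_config`.
#' @export
linking_config <- function(max_linking_distance = 0.3,
                           alternative_cost_factor = 1.05) {
  stopifnot(max_linking_distance > 0, alternative_cost_factor > 1)
  structure(
    list(
      max_linking_distance = max_linking_distance,
      alternative_cost_factor = alternative_cost_factor
    ),
    class = "linking_config"
  )
}

#' Full pipeline configuration
#'
#' @param pixel_size Pixel size, um/px.
#' @param frame_interval Frame interval, s.
#' @param detection A [detection_config()].
#' @param linking A [linking_config()].
#' @param msd_n_max Number of MSD lags (default 10, i.e. 0.03-0.30 s at
#'   30 ms).
#' @param min_spots,max_spots Track-length bounds for analysis (defaults 6
#'   and 1000).
#' @param peak_lag Lag (s) treated as the mobility peak for normalization
#'   and delta mobility (default 0.30 s); must sit on the lag grid.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 0.1,
                            frame_interval = 0.03,
                            detection = detection_config(),
                            linking = linking_config(),
                            msd_n_max = 10L,
                            min_spots = 6L,
                            max_spots = 1000L,
                            peak_lag = 0.30) {
  stopifnot(
    pixel_size > 0, frame_interval > 0,
    inherits(detection, "detection_config"),
    inherits(linking, "linking_config"),
    msd_n_max >= 4, min_spots >= 2, max_spots >= min_spots,
    peak_lag > 0
  )
  lag_grid <- frame_interval * seq_len(msd_n_max)
  if (min(abs(lag_grid - peak_lag)) > 1e-9) {
    stop("peak_lag must be a multiple of frame_interval within msd_n_max lags",
      call. = FALSE
    )
  }
  structure(
    list(
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      detection = detection,
      linking = linking,
      msd_n_max = as.integer(msd_n_max),
      min_spots = as.integer(min_spots),
      max_spots = as.integer(max_spots),
      peak_lag = peak_lag
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()];
#' `detection:` and `linking:` sub-maps mirror [detection_config()] and
#' [linking_config()]. Missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  det <- do.call(detection_config, raw$detection %||% list())
  lnk <- do.call(linking_config, raw$linking %||% list())
  top <- raw[setdiff(names(raw), c("detection", "linking"))]
  do.call(pipeline_config, c(top, list(detection = det, linking = lnk)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
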