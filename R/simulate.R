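# Ground-truth sptPALM simulator: Brownian trajectories + four-state
# photophysics + Gaussian PSF rendering + EMCCD-style noise + stage drift.

#' Simulate ground-truth molecule trajectories and photophysics
#'
#' Draws, for every molecule in the unconverted pool, a photoconversion
#' frame (geometric in `conversion_rate`), then runs the on/dark/bleached
#' chain forward and a 2D Brownian walk while the molecule is alive. Each
#' axis displacement per frame is N(0, 2 D dt). Molecules never converted
#' within the movie are omitted. With `site_positions` set and a finite
#' `confinement_radius`, molecules start near a site and reflect off a
#' square box around it, emulating membrane compartments.
#'
#' @param config A [sim_config()].
#' @return An object of class `spt_truth`: a list with `config`,
#'   `molecules` (tibble: molecule_id, population, true_D, convert_frame,
#'   end_frame) and `positions` (tibble: molecule_id, frame, x_um, y_um,
#'   state, true_D; state is `"on"` or `"dark"`, bleached frames are not
#'   listed).
#' @examples
#' cfg <- sim_config(n_frames = 50, n_molecules = 500, seed = 7)
#' truth <- simulate_trajectories(cfg)
#' dplyr::count(truth$positions, .data$state)
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_trajectories_impl(config))
}

simulate_trajectories_impl <- function(config) {
  n_frames <- config$n_frames
  dt <- config$frame_interval
  fov_um <- (config$image_size - 1L) * config$pixel_size # c(height, width)

  if (config$conversion_rate <= 0) {
    convert <- integer(0)
  } else {
    convert <- rgeom(config$n_molecules, config$conversion_rate) + 1L
  }
  alive <- which(convert <= n_frames)
  if (length(alive) == 0) {
    return(new_spt_truth(config, empty_molecules(), empty_positions()))
  }
  convert <- convert[alive]
  n <- length(alive)

  pops <- sample.int(nrow(config$D_populations), n,
    replace = TRUE, prob = config$D_populations$fraction
  )
  D <- config$D_populations$D[pops]

  has_sites <- !is.null(config$site_positions)
  if (has_sites) {
    site_idx <- sample.int(nrow(config$site_positions), n, replace = TRUE)
    cx <- config$site_positions$x_um[site_idx]
    cy <- config$site_positions$y_um[site_idx]
    r <- min(config$confinement_radius, min(fov_um) / 2)
    x0 <- cx + runif(n, -r, r)
    y0 <- cy + runif(n, -r, r)
  } else {
    x0 <- runif(n, 0, fov_um[2])
    y0 <- runif(n, 0, fov_um[1])
    cx <- x0
    cy <- y0
  }

  per_mol <- vector("list", n)
  for (i in seq_len(n)) {
    states <- simulate_photostates(
      n_frames - convert[i] + 1L,
      config$bleach_rate, config$blink_off_rate, config$blink_on_rate
    )
    n_alive <- length(states)
    if (n_alive == 0L) next
    frames <- seq.int(convert[i], length.out = n_alive)
    sdev <- sqrt(2 * D[i] * dt)
    x <- x0[i] + c(0, cumsum(rnorm(n_alive - 1L, 0, sdev)))
    y <- y0[i] + c(0, cumsum(rnorm(n_alive - 1L, 0, sdev)))
    if (is.finite(config$confinement_radius)) {
      r <- min(config$confinement_radius, min(fov_um) / 2)
      x <- reflect_fold(x, cx[i] - r, cx[i] + r)
      y <- reflect_fold(y, cy[i] - r, cy[i] + r)
    }
    per_mol[[i]] <- tibble::tibble(
      molecule_id = i, frame = frames, x_um = x, y_um = y,
      state = c("on", "dark")[states], true_D = D[i]
    )
  }
  positions <- dplyr::bind_rows(per_mol)
  kept <- unique(positions$molecule_id)
  molecules <- tibble::tibble(
    molecule_id = seq_len(n),
    population = pops,
    true_D = D,
    convert_frame = convert
  ) |>
    dplyr::semi_join(
      tibble::tibble(molecule_id = kept),
      by = "molecule_id"
    ) |>
    dplyr::left_join(
      dplyr::summarise(
        dplyr::group_by(positions, .data$molecule_id),
        end_frame = max(.data$frame), .groups = "drop"
      ),
      by = "molecule_id"
    )
  new_spt_truth(config, molecules, positions)
}

# Markov chain over (on = 1, dark = 2); returns the state per frame until
# bleaching (absorbing) or the frame budget runs out.
simulate_photostates <- function(max_frames, bleach, blink_off, blink_on) {
  states <- integer(max_frames)
  s <- 1L
  t <- 0L
  while (t < max_frames) {
    t <- t + 1L
    states[t] <- s
    if (s == 1L) {
      u <- runif(1)
      if (u < bleach) {
        return(states[seq_len(t)])
      } else if (u < bleach + blink_off) {
        s <- 2L
      }
    } else {
      if (runif(1) < blink_on) s <- 1L
    }
  }
  states
}

# Fold an unconstrained path into [lo, hi] by reflection (triangular map);
# folding the free Brownian path yields reflected Brownian motion.
reflect_fold <- function(z, lo, hi) {
  w <- hi - lo
  if (w <= 0) {
    return(rep((lo + hi) / 2, length(z)))
  }
  u <- (z - lo) %% (2 * w)
  lo + ifelse(u > w, 2 * w - u, u)
}

new_spt_truth <- function(config, molecules, positions) {
  structure(
    list(config = config, molecules = molecules, positions = positions),
    class = "spt_truth"
  )
}

empty_molecules <- function() {
  tibble::tibble(
    molecule_id = integer(0), population = integer(0), true_D = numeric(0),
    convert_frame = integer(0), end_frame = integer(0)
  )
}

empty_positions <- function() {
  tibble::tibble(
    molecule_id = integer(0), frame = integer(0), x_um = numeric(0),
    y_um = numeric(0), state = character(0), true_D = numeric(0)
  )
}

#' @export
print.spt_truth <- function(x, ...) {
  cat(
    "<spt_truth> ", nrow(x$molecules), " molecules over ",
    x$config$n_frames, " frames; ",
    nrow(x$positions), " molecule-frames\n",
    sep = ""
  )
  invisible(x)
}

#' Ground-truth observable tracks with localization noise
#'
#' Converts the "on" frames of a ground truth into the tracks an ideal
#' detector/tracker would recover: each maximal run of consecutive on
#' frames becomes one track (a blink ends a track, since linking does no
#' gap closing), and independent Gaussian localization noise of the given
#' standard deviation is added to each coordinate.
#'
#' @param truth An `spt_truth`.
#' @param sigma_loc Localization noise SD in micrometres per axis
#'   (default 0.018, i.e. 18 nm).
#' @param seed Optional seed for the noise draw; default derives from the
#'   simulation seed.
#' @return A track tibble (class `spt_tracks`) with columns track_id,
#'   frame, x_um, y_um, x_px, y_px, molecule_id, true_D, and attributes
#'   `pixel_size`, `frame_interval`.
#' @export
truth_tracks <- function(truth, sigma_loc = 0.018, seed = NULL) {
  stopifnot(inherits(truth, "spt_truth"), sigma_loc >= 0)
  seed <- seed %||% (truth$config$seed + 90001L)
  on_pos <- dplyr::filter(truth$positions, .data$state == "on")
  if (nrow(on_pos) == 0) {
    return(new_spt_tracks(
      tibble::tibble(
        track_id = integer(0), frame = integer(0), x_um = numeric(0),
        y_um = numeric(0), x_px = numeric(0), y_px = numeric(0),
        molecule_id = integer(0), true_D = numeric(0)
      ),
      truth$config$pixel_size, truth$config$frame_interval
    ))
  }
  on_pos <- dplyr::arrange(on_pos, .data$molecule_id, .data$frame)
  # segment id increments at every gap in the frame sequence or new molecule
  new_seg <- c(
    TRUE,
    diff(on_pos$frame) != 1L |
      diff(on_pos$molecule_id) != 0L
  )
  on_pos$track_id <- cumsum(new_seg)
  noisy <- with_seed(seed, {
    on_pos$x_um <- on_pos$x_um + rnorm(nrow(on_pos), 0, sigma_loc)
    on_pos$y_um <- on_pos$y_um + rnorm(nrow(on_pos), 0, sigma_loc)
    on_pos
  })
  px <- truth$config$pixel_size
  out <- tibble::tibble(
    track_id = noisy$track_id,
    frame = noisy$frame,
    x_um = noisy$x_um,
    y_um = noisy$y_um,
    x_px = noisy$x_um / px,
    y_px = noisy$y_um / px,
    molecule_id = noisy$molecule_id,
    true_D = noisy$true_D
  )
  new_spt_tracks(out, px, truth$config$frame_interval)
}

#' Render a ground truth into a noisy movie
#'
#' Every "on" molecule contributes a 2D Gaussian PSF of the configured half
#' width sampled at pixel centres, scaled to its mean photon budget. The
#' camera model is Poisson shot noise on signal + background, multiplied by
#' the gain, plus Gaussian read noise, rounded and clipped to 16-bit range.
#'
#' @param truth An `spt_truth`.
#' @param config A [sim_config()]; defaults to the one inside `truth`.
#' @param seed Seed for the noise draws; default derives from the
#'   simulation seed so that `simulate_movie()` is reproducible end to end.
#' @return An [spt_movie()] of `config$n_frames` frames.
#' @export
render_movie <- function(truth, config = truth$config, seed = NULL) {
  stopifnot(inherits(truth, "spt_truth"), inherits(config, "sim_config"))
  seed <- seed %||% (config$seed + 1L)
  with_seed(seed, render_movie_impl(truth, config))
}

render_movie_impl <- function(truth, config) {
  h <- config$image_size[1]
  w <- config$image_size[2]
  sigma <- psf_sigma_px(config)
  r <- max(3L, as.integer(ceiling(4 * sigma)))
  on_pos <- dplyr::filter(truth$positions, .data$state == "on")
  by_frame <- split(on_pos, factor(on_pos$frame, levels = seq_len(config$n_frames)))

  frames <- vector("list", config$n_frames)
  norm <- config$photons_per_frame / (2 * pi * sigma^2)
  for (t in seq_len(config$n_frames)) {
    lambda <- matrix(config$background, nrow = h, ncol = w)
    mols <- by_frame[[t]]
    if (!is.null(mols) && nrow(mols) > 0) {
      xs <- mols$x_um / config$pixel_size # 0-based px
      ys <- mols$y_um / config$pixel_size
      for (k in seq_len(nrow(mols))) {
        cx <- xs[k]
        cy <- ys[k]
        j0 <- max(1L, floor(cx) + 1L - r)
        j1 <- min(w, floor(cx) + 1L + r)
        i0 <- max(1L, floor(cy) + 1L - r)
        i1 <- min(h, floor(cy) + 1L + r)
        if (j0 > j1 || i0 > i1) next
        jj <- j0:j1
        ii <- i0:i1
        gx <- exp(-((jj - 1L) - cx)^2 / (2 * sigma^2))
        gy <- exp(-((ii - 1L) - cy)^2 / (2 * sigma^2))
        lambda[ii, jj] <- lambda[ii, jj] + norm * outer(gy, gx)
      }
    }
    dn <- rpois(h * w, lambda) * config$em_gain
    if (config$read_noise > 0) {
      dn <- dn + rnorm(h * w, 0, config$read_noise * config$em_gain)
    }
    frames[[t]] <- matrix(pmin(pmax(round(dn), 0), 65535L), nrow = h)
  }
  spt_movie(
    array(unlist(frames), dim = c(h, w, config$n_frames)),
    pixel_size = config$pixel_size,
    frame_interval = config$frame_interval
  )
}

#' Apply linear stage drift to a movie
#'
#' Frame t is translated by `(t - 1) * drift_velocity` pixels (x then y,
#' x along columns) using bilinear interpolation with replicated edges, so
#' the first frame is untouched and zero drift returns the input movie
#' unchanged.
#'
#' @param movie An [spt_movie()].
#' @param drift_velocity Length-2 numeric, px/frame along (x, y).
#' @return A drifted [spt_movie()] (integer-valued, like its input).
#' @export
inject_drift <- function(movie, drift_velocity) {
  stopifnot(inherits(movie, "spt_movie"), length(drift_velocity) == 2,
    all(is.finite(drift_velocity)))
  if (all(drift_velocity == 0)) {
    return(movie)
  }
  d <- dim(movie)
  out <- movie
  for (t in seq_len(d[3])) {
    sh <- (t - 1) * drift_velocity
    if (all(sh == 0)) next
    out[, , t] <- round(translate_bilinear(movie[, , t], sh[1], sh[2]))
  }
  out
}

# Translate an image by (dx, dy) pixels: output(x, y) = input(x - dx, y - dy)
# with bilinear interpolation and clamped (replicate) borders.
translate_bilinear <- function(img, dx, dy) {
  h <- nrow(img)
  w <- ncol(img)
  xs <- (seq_len(w) - 1) - dx
  ys <- (seq_len(h) - 1) - dy
  x0 <- pmin(pmax(floor(xs), 0), w - 1)
  y0 <- pmin(pmax(floor(ys), 0), h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  a <- img[y0 + 1, x0 + 1, drop = FALSE]
  b <- img[y0 + 1, x1 + 1, drop = FALSE]
  cc <- img[y1 + 1, x0 + 1, drop = FALSE]
  dd <- img[y1 + 1, x1 + 1, drop = FALSE]
  wx <- matrix(fx, nrow = h, ncol = w, byrow = TRUE)
  wy <- matrix(fy, nrow = h, ncol = w)
  (a * (1 - wx) + b * wx) * (1 - wy) + (cc * (1 - wx) + dd * wx) * wy
}

#' Simulate a complete movie with ground truth
#'
#' Convenience wrapper: [simulate_trajectories()], [render_movie()], and
#' [inject_drift()] when the configured drift is nonzero. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `truth` (spt_truth) and `movie`
#'   ([spt_movie()]).
#' @export
simulate_movie <- function(config) {
  truth <- simulate_trajectories(config)
  movie <- render_movie(truth, config)
  if (any(config$drift_velocity != 0)) {
    movie <- inject_drift(movie, config$drift_velocity)
  }
  list(truth = truth, movie = movie)
}

#' Simulate an internally controlled paired recording
#'
#' Emulates the paired experimental design: the same field is recorded
#' twice, a baseline and a treatment recording, with shared confinement
#' sites giving both maximum projections a common spatial structure. In the
#' treatment recording every molecule's diffusion coefficient is multiplied
#' by `stim_factor` with probability equal to the field-of-view overlap
#' that remains after stage drift: total drift of (Dx, Dy) pixels slides
#' the imaged region so only a fraction
#' `(1 - |Dx|/W) * (1 - |Dy|/H)` of it still covers the stimulated site,
#' and molecules outside that overlap stay at baseline mobility. The
#' treatment movie itself is rendered and then drifted, so drift lowers
#' both the max-projection Pearson correlation and the detectable mobility
#' response, as seen in drifting tissue recordings.
#'
#' @param config A [sim_config()] for one recording; its seed separates the
#'   two recordings deterministically.
#' @param stim_factor Multiplier applied to stimulated molecules' D in the
#'   treatment recording (default 2; use values < 1 or a raised immobile
#'   fraction via `treatment_D_populations` for immobilizing treatments).
#' @param drift_velocity Drift of the treatment recording, px/frame.
#' @param treatment_D_populations Optional replacement diffusion mixture
#'   for the treatment recording (overrides `stim_factor`).
#' @param n_sites Number of shared confinement sites.
#' @param render Render movies (`TRUE`, default) or return truths only.
#' @return List with `baseline` and `treatment`, each a list of `truth`
#'   and (if `render`) `movie`; plus `stimulated_fraction`.
#' @export
simulate_paired_recording <- function(config,
                                      stim_factor = 2,
                                      drift_velocity = c(0, 0),
                                      treatment_D_populations = NULL,
                                      n_sites = 60L,
                                      render = TRUE) {
  stopifnot(inherits(config, "sim_config"), stim_factor > 0)
  fov_um <- (config$image_size - 1L) * config$pixel_size
  sites <- with_seed(config$seed + 77L, tibble::tibble(
    x_um = runif(n_sites, 0.05 * fov_um[2], 0.95 * fov_um[2]),
    y_um = runif(n_sites, 0.05 * fov_um[1], 0.95 * fov_um[1])
  ))

  base_cfg <- config
  base_cfg$site_positions <- sites
  if (!is.finite(base_cfg$confinement_radius)) {
    base_cfg$confinement_radius <- 0.4
  }
  base_cfg$drift_velocity <- c(0, 0)

  total_drift <- abs(drift_velocity) * (config$n_frames - 1)
  overlap <- prod(pmax(0, 1 - total_drift / rev(config$image_size)))

  treat_cfg <- base_cfg
  treat_cfg$seed <- config$seed + 1000L
  if (!is.null(treatment_D_populations)) {
    stim_pops <- tibble::as_tibble(treatment_D_populations)
  } else {
    stim_pops <- base_cfg$D_populations
    stim_pops$D <- stim_pops$D * stim_factor
  }
  # mixture: stimulated (overlap) vs baseline-mobility (slid-off) molecules
  treat_cfg$D_populations <- dplyr::bind_rows(
    dplyr::mutate(stim_pops, fraction = .data$fraction * overlap),
    dplyr::mutate(base_cfg$D_populations,
      fraction = .data$fraction * (1 - overlap)
    )
  )
  treat_cfg$drift_velocity <- as.numeric(drift_velocity)

  baseline <- if (render) simulate_movie(base_cfg) else
    list(truth = simulate_trajectories(base_cfg))
  treatment <- if (render) simulate_movie(treat_cfg) else
    list(truth = simulate_trajectories(treat_cfg))
  list(
    baseline = baseline, treatment = treatment,
    stimulated_fraction = overlap, sites = sites
  )
}

#' Ground truth of static, always-on emitters at given positions
#'
#' Builds an `spt_truth` whose molecules sit at fixed positions and stay
#' "on" for every frame: the controlled layout used to characterise
#' detection recall, precision and localization error against known
#' coordinates.
#'
#' @param positions Tibble with `x_um`, `y_um`.
#' @param config A [sim_config()] providing frame count, calibration and
#'   camera settings for rendering.
#' @return An `spt_truth`.
#' @export
static_spot_truth <- function(positions, config) {
  stopifnot(inherits(config, "sim_config"),
    all(c("x_um", "y_um") %in% names(positions)))
  n <- nrow(positions)
  positions <- tibble::as_tibble(positions)
  pos <- tidyr::crossing(
    molecule_id = seq_len(n),
    frame = seq_len(config$n_frames)
  ) |>
    dplyr::mutate(
      x_um = positions$x_um[.data$molecule_id],
      y_um = positions$y_um[.data$molecule_id],
      state = "on",
      true_D = 0
    )
  molecules <- tibble::tibble(
    molecule_id = seq_len(n), population = 1L, true_D = 0,
    convert_frame = 1L, end_frame = config$n_frames
  )
  new_spt_truth(config, molecules, pos)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
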