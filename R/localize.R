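# Spot detection and subpixel localization: 3x3 median prefilter,
# scale-normalized Laplacian-of-Gaussian response, local-maximum picking
# with non-maximum suppression, and per-spot 2D Gaussian least-squares
# refinement that also yields the localization-precision estimate.

#' Scale-normalized Laplacian-of-Gaussian kernel
#'
#' Built from the Gaussian kernel g(x, y, t) = exp(-(x^2+y^2)/(2t)) / (2
#' pi t) with t = `log_sigma`^2. The kernel is the negated,
#' scale-normalized Laplacian -t * (g_xx + g_yy), so bright blobs of
#' matching scale produce positive maxima, and it is mean-subtracted so a
#' constant image maps exactly to zero.
#'
#' @param log_sigma Blob scale in pixels (Gaussian sigma).
#' @param radius Kernel half-size in px; default `ceiling(4 * log_sigma)`.
#' @return A square numeric matrix of side `2 * radius + 1`.
#' @export
log_kernel <- function(log_sigma, radius = ceiling(4 * log_sigma)) {
  stopifnot(log_sigma > 0)
  s2 <- log_sigma^2
  u <- seq(-radius, radius)
  r2 <- outer(u^2, u^2, "+")
  g <- exp(-r2 / (2 * s2)) / (2 * pi * s2)
  k <- (2 - r2 / s2) * g # = -t * laplacian(g)
  k - mean(k)
}

#' Laplacian-of-Gaussian filter response
#'
#' Convolves a frame with [log_kernel()] (replicated borders). The sign
#' convention makes bright blobs positive; the mean-free kernel
#' annihilates constant offsets, so detection is invariant to adding a
#' constant to the frame.
#'
#' @param frame Numeric matrix.
#' @param log_sigma Blob scale in pixels.
#' @return Response matrix of the same size.
#' @export
log_filter <- function(frame, log_sigma) {
  stopifnot(is.matrix(frame), all(is.finite(frame)), log_sigma > 0)
  k <- log_kernel(log_sigma)
  if (min(dim(frame)) <= nrow(k)) {
    return(conv2_replicate(frame, k))
  }
  EBImage::filter2(frame, k, boundary = "replicate")
}

# Direct (non-FFT) 2D correlation with replicate padding; used for frames
# smaller than the kernel, where the FFT path cannot be applied.
conv2_replicate <- function(frame, k) {
  r <- (nrow(k) - 1L) %/% 2L
  h <- nrow(frame)
  w <- ncol(frame)
  ri <- pmin(pmax(seq(1 - r, h + r), 1), h)
  ci <- pmin(pmax(seq(1 - r, w + r), 1), w)
  pad <- frame[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- sum(pad[i:(i + 2 * r), j:(j + 2 * r)] * k)
    }
  }
  out
}

#' 3x3 median filter
#'
#' Exact median-of-9 computed with a vectorized sorting network over the
#' nine shifted copies of the image (replicated borders); used as the
#' standard despeckling prefilter before LoG detection.
#'
#' @param frame Numeric matrix.
#' @return Filtered matrix of the same size.
#' @export
median_filter3 <- function(frame) {
  stopifnot(is.matrix(frame))
  h <- nrow(frame)
  w <- ncol(frame)
  ri <- function(o) pmin(pmax(seq_len(h) + o, 1), h)
  ci <- function(o) pmin(pmax(seq_len(w) + o, 1), w)
  p <- vector("list", 9)
  idx <- 1
  for (dy in -1:1) {
    for (dx in -1:1) {
      p[[idx]] <- frame[ri(dy), ci(dx), drop = FALSE]
      idx <- idx + 1
    }
  }
  swap <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]])
    hi <- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo
    p[[b]] <<- hi
  }
  # Paeth's 19-exchange median-of-9 network; median ends in slot 5
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 4); swap(6, 9); swap(5, 8)
  swap(4, 7); swap(2, 5); swap(3, 6)
  swap(5, 8); swap(5, 3); swap(7, 5)
  swap(5, 3)
  p[[5]]
}

#' Detect candidate spots in one frame
#'
#' Optional 3x3 median prefilter, LoG response at the configured scale,
#' then local maxima above the quality threshold with non-maximum
#' suppression within one `log_sigma` radius. Candidates closer than half
#' the refinement window to any border are discarded.
#'
#' @param frame Numeric matrix.
#' @param config A [detection_config()].
#' @param quality_threshold Optional override of the configured threshold
#'   (useful when the automatic threshold was fixed on a reference frame).
#' @return Tibble with columns `x_px`, `y_px` (integer, 0-based pixel
#'   coordinates) and `quality` (LoG response at the maximum), ordered by
#'   decreasing quality. May be empty.
#' @export
detect_spots <- function(frame, config = detection_config(),
                         quality_threshold = NULL) {
  stopifnot(is.matrix(frame), inherits(config, "detection_config"))
  f <- if (config$use_median_filter) median_filter3(frame) else frame
  resp <- log_filter(f, config$log_sigma)
  thr <- quality_threshold %||% config$quality_threshold %||%
    auto_threshold(resp, config$auto_quantile)
  r <- max(1L, as.integer(ceiling(config$log_sigma)))
  is_max <- local_maxima(resp, r)
  border <- config$refine_window %/% 2L
  h <- nrow(frame)
  w <- ncol(frame)
  keep <- which(is_max & resp >= thr, arr.ind = TRUE)
  if (nrow(keep) > 0) {
    ok <- keep[, 1] > border & keep[, 1] <= h - border &
      keep[, 2] > border & keep[, 2] <= w - border
    keep <- keep[ok, , drop = FALSE]
  }
  out <- tibble::tibble(
    x_px = as.integer(keep[, 2] - 1L),
    y_px = as.integer(keep[, 1] - 1L),
    quality = resp[keep]
  )
  dplyr::arrange(out, dplyr::desc(.data$quality))
}

#' Automatic detection threshold from a reference frame response
#'
#' Upper quantile of the LoG response, the stand-in for the per-recording
#' manual threshold of the original analysis.
#'
#' @param response LoG response matrix (from [log_filter()]).
#' @param auto_quantile Quantile, default 0.9995.
#' @return Threshold value.
#' @export
auto_threshold <- function(response, auto_quantile = 0.9995) {
  as.numeric(quantile(response, auto_quantile, names = FALSE))
}

# TRUE where a pixel is the strict-or-tied maximum of its (2r+1)^2
# neighbourhood, ties broken toward the top-left so that a plateau yields
# one candidate.
local_maxima <- function(resp, r) {
  h <- nrow(resp)
  w <- ncol(resp)
  is_max <- matrix(TRUE, h, w)
  ri <- function(o) pmin(pmax(seq_len(h) + o, 1), h)
  ci <- function(o) pmin(pmax(seq_len(w) + o, 1), w)
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0 && dx == 0) next
      nb <- resp[ri(dy), ci(dx), drop = FALSE]
      if (dy < 0 || (dy == 0 && dx < 0)) {
        is_max <- is_max & (resp > nb) # earlier neighbour must be beaten
      } else {
        is_max <- is_max & (resp >= nb)
      }
    }
  }
  is_max
}

#' Subpixel Gaussian refinement of detected spots
#'
#' Fits `b + A exp(-((x-x0)^2 + (y-y0)^2) / (2 s^2))` by least squares
#' (Levenberg-Marquardt, analytic Jacobian) in a `refine_window` square
#' around each candidate. The localization-precision estimate is the mean
#' of the fitted standard errors of x0 and y0 (from the fit covariance),
#' which scales as PSF width / sqrt(photons). Fits that fail to converge,
#' wander out of the window, or end at an implausible width are dropped;
#' the number dropped is recorded in the `n_dropped` attribute.
#'
#' @param frame Numeric matrix.
#' @param candidates Tibble from [detect_spots()].
#' @param config A [detection_config()].
#' @param pixel_size Pixel size (um/px) used for micron coordinates and
#'   nm-scale precision.
#' @return Tibble of localizations: `x_px`, `y_px` (subpixel), `x_um`,
#'   `y_um`, `intensity` (integrated Gaussian volume, camera units),
#'   `quality`, `sigma_px` (fitted width), `precision_nm`.
#' @export
refine_subpixel <- function(frame, candidates, config = detection_config(),
                            pixel_size = 0.1) {
  stopifnot(is.matrix(frame), inherits(config, "detection_config"))
  half <- config$refine_window %/% 2L
  n <- nrow(candidates)
  res <- vector("list", n)
  n_dropped <- 0L
  for (i in seq_len(n)) {
    cx <- candidates$x_px[i]
    cy <- candidates$y_px[i]
    rows <- (cy - half):(cy + half) + 1L
    cols <- (cx - half):(cx + half) + 1L
    if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > nrow(frame) || max(cols) > ncol(frame)) {
      n_dropped <- n_dropped + 1L
      next
    }
    fit <- fit_gaussian_spot(
      frame[rows, cols], cx - half, cy - half, config$log_sigma
    )
    if (is.null(fit)) {
      n_dropped <- n_dropped + 1L
      next
    }
    # reject fits that left the window or degenerated
    if (abs(fit$x0 - cx) > half || abs(fit$y0 - cy) > half ||
      fit$sigma < 0.3 || fit$sigma > 4 * config$log_sigma ||
      fit$amp <= 0 || fit$precision_px > half) {
      n_dropped <- n_dropped + 1L
      next
    }
    res[[i]] <- tibble::tibble(
      x_px = fit$x0, y_px = fit$y0,
      x_um = fit$x0 * pixel_size, y_um = fit$y0 * pixel_size,
      intensity = 2 * pi * fit$amp * fit$sigma^2,
      quality = candidates$quality[i],
      sigma_px = fit$sigma,
      precision_nm = fit$precision_px * pixel_size * 1000
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      x_px = numeric(0), y_px = numeric(0), x_um = numeric(0),
      y_um = numeric(0), intensity = numeric(0), quality = numeric(0),
      sigma_px = numeric(0), precision_nm = numeric(0)
    )
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

# Least-squares symmetric-Gaussian fit on a window whose top-left pixel is
# (x_off, y_off) in 0-based image coordinates. Returns NULL if the fit
# fails.
fit_gaussian_spot <- function(win, x_off, y_off, sigma0) {
  wsz <- nrow(win)
  px <- rep(seq_len(wsz) - 1, each = wsz) + x_off # column-major: x varies slowly
  py <- rep(seq_len(wsz) - 1, times = wsz) + y_off
  z <- as.numeric(win)
  bg0 <- min(z)
  amp0 <- max(z) - bg0
  if (amp0 <= 0) {
    return(NULL)
  }
  ctr <- c(x_off + (wsz - 1) / 2, y_off + (wsz - 1) / 2)
  model <- function(p) {
    p[1] + p[2] * exp(-((px - p[3])^2 + (py - p[4])^2) / (2 * p[5]^2))
  }
  jac <- function(p) {
    e <- exp(-((px - p[3])^2 + (py - p[4])^2) / (2 * p[5]^2))
    cbind(
      1, e,
      p[2] * e * (px - p[3]) / p[5]^2,
      p[2] * e * (py - p[4]) / p[5]^2,
      p[2] * e * ((px - p[3])^2 + (py - p[4])^2) / p[5]^3
    )
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(bg0, amp0, ctr[1], ctr[2], sigma0),
      fn = function(p) z - model(p),
      jac = function(p) -jac(p),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$info %in% c(0, 9)) {
    return(NULL)
  }
  p <- fit$par
  dof <- length(z) - 5L
  s2 <- sum(fit$fvec^2) / max(dof, 1L)
  cov_xy <- tryCatch(
    {
      cv <- solve(fit$hessian) * s2
      sqrt(pmax(diag(cv)[3:4], 0))
    },
    error = function(e) c(NA_real_, NA_real_)
  )
  if (any(!is.finite(cov_xy))) {
    return(NULL)
  }
  list(
    bg = p[1], amp = p[2], x0 = p[3], y0 = p[4], sigma = abs(p[5]),
    precision_px = mean(cov_xy)
  )
}

#' Localize all frames of a movie
#'
#' Runs [detect_spots()] and [refine_subpixel()] frame by frame. When no
#' explicit threshold is configured, the automatic threshold is fixed once
#' on the reference frame and reused for the whole recording, mimicking a
#' single per-recording manual threshold.
#'
#' @param movie An [spt_movie()].
#' @param config A [detection_config()].
#' @param reference_frame Frame used to fix the automatic threshold
#'   (default 1).
#' @return Tibble of localizations with a leading `frame` column; the
#'   threshold used is stored in the `quality_threshold` attribute and the
#'   total dropped-fit count in `n_dropped`.
#' @export
localize_movie <- function(movie, config = detection_config(),
                           reference_frame = 1L) {
  stopifnot(inherits(movie, "spt_movie"))
  px <- attr(movie, "pixel_size")
  thr <- config$quality_threshold
  if (is.null(thr)) {
    f <- unclass(movie)[, , reference_frame]
    if (config$use_median_filter) f <- median_filter3(f)
    thr <- auto_threshold(log_filter(f, config$log_sigma), config$auto_quantile)
  }
  n_frames <- dim(movie)[3]
  out <- vector("list", n_frames)
  n_dropped <- 0L
  for (t in seq_len(n_frames)) {
    frame <- unclass(movie)[, , t]
    cands <- detect_spots(frame, config, quality_threshold = thr)
    locs <- refine_subpixel(frame, cands, config, pixel_size = px)
    n_dropped <- n_dropped + attr(locs, "n_dropped")
    if (nrow(locs) > 0) {
      out[[t]] <- dplyr::bind_cols(tibble::tibble(frame = t), locs)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(
      frame = integer(0), x_px = numeric(0), y_px = numeric(0),
      x_um = numeric(0), y_um = numeric(0), intensity = numeric(0),
      quality = numeric(0), sigma_px = numeric(0), precision_nm = numeric(0)
    )
  }
  attr(res, "quality_threshold") <- thr
  attr(res, "n_dropped") <- n_dropped
  attr(res, "pixel_size") <- px
  attr(res, "frame_interval") <- attr(movie, "frame_interval")
  res
}

#' Summarise localization precision and PSF width
#'
#' @param localizations Tibble from [localize_movie()] or
#'   [refine_subpixel()] (needs `sigma_px` and `precision_nm`).
#' @param pixel_size Pixel size, um/px (default: taken from the attribute
#'   set by [localize_movie()], else 0.1).
#' @return One-row tibble: n, mean/sd of precision (nm) and of the PSF
#'   half width (fitted FWHM/2, nm).
#' @export
estimate_localization_stats <- function(localizations, pixel_size = NULL) {
  if (nrow(localizations) == 0) {
    stop("no localizations to summarise", call. = FALSE)
  }
  pixel_size <- pixel_size %||% attr(localizations, "pixel_size") %||% 0.1
  half_width_nm <- localizations$sigma_px * sqrt(2 * log(2)) *
    pixel_size * 1000
  tibble::tibble(
    n = nrow(localizations),
    precision_mean_nm = mean(localizations$precision_nm),
    precision_sd_nm = sd(localizations$precision_nm),
    psf_half_width_mean_nm = mean(half_width_nm),
    psf_half_width_sd_nm = sd(half_width_nm)
  )
}
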