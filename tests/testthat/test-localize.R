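# LoG filtering, spot detection and subpixel Gaussian refinement.

test_that("LoG response is zero for zero and constant frames", {
  z <- matrix(0, 24, 24)
  expect_true(all(log_filter(z, 1.2) == 0))
  flat <- matrix(7.5, 24, 24)
  expect_lt(max(abs(log_filter(flat, 1.2))), 1e-9)
})

test_that("LoG response matches a dense direct-convolution oracle", {
  set.seed(31)
  img <- matrix(rnorm(18 * 15), 18, 15)
  k <- log_kernel(1.0)
  expect_equal(log_filter(img, 1.0), dense_conv_oracle(img, k),
    tolerance = 1e-10
  )
})

test_that("LoG maximum sits at the centre of a matched Gaussian spot", {
  img <- spot_frame(25, 25, x0 = 11, y0 = 13, amp = 10, sigma = 1.3)
  resp <- log_filter(img, 1.3)
  peak <- which(resp == max(resp), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(14, 12)) # row = y + 1, col = x + 1
})

test_that("detection is empty on background and exact on separated spots", {
  cfg <- detection_config(log_sigma = 1.2, quality_threshold = 2)
  set.seed(41)
  noise <- matrix(rnorm(40 * 40, 10, 1), 40, 40)
  expect_equal(nrow(detect_spots(noise, cfg)), 0)

  two <- noise + spot_frame(40, 40,
    x0 = c(12, 22), y0 = c(20, 20),
    amp = c(40, 40), sigma = c(1.2, 1.2)
  )
  found <- detect_spots(two, cfg)
  expect_equal(nrow(found), 2)
  expect_setequal(found$x_px, c(12, 22))
})

test_that("candidate count is non-increasing in the threshold", {
  set.seed(42)
  frame <- matrix(rnorm(50 * 50, 10, 2), 50, 50) +
    spot_frame(50, 50,
      x0 = c(10, 25, 40), y0 = c(10, 30, 15),
      amp = 30, sigma = 1.2
    )
  cfg <- function(thr) detection_config(log_sigma = 1.2, quality_threshold = thr)
  counts <- vapply(
    c(-5, 0, 1, 3, 8, 20),
    function(t) nrow(detect_spots(frame, cfg(t))),
    integer(1)
  )
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[2], 3) # threshold 0 on noise admits many candidates
})

test_that("adding a constant to the frame leaves detections unchanged", {
  set.seed(43)
  frame <- matrix(rnorm(40 * 40, 5, 1), 40, 40) +
    spot_frame(40, 40, x0 = c(15, 28), y0 = c(12, 25), amp = 25, sigma = 1.1)
  cfg <- detection_config(log_sigma = 1.1, quality_threshold = 2)
  d1 <- detect_spots(frame, cfg)
  d2 <- detect_spots(frame + 123.4, cfg)
  expect_equal(d1$x_px, d2$x_px)
  expect_equal(d1$y_px, d2$y_px)
  expect_equal(d1$quality, d2$quality, tolerance = 1e-8)
})

test_that("subpixel refinement recovers an off-grid position to 0.1 px", {
  frame <- spot_frame(50, 50,
    x0 = 25.30, y0 = 40.70 - 10, amp = 200,
    sigma = 1.1, bg = 10
  )
  set.seed(44)
  frame <- frame + rnorm(length(frame), 0, 1)
  cfg <- detection_config(log_sigma = 1.1, quality_threshold = 10)
  cands <- detect_spots(frame, cfg)
  expect_gte(nrow(cands), 1)
  locs <- refine_subpixel(frame, cands[1, ], cfg, pixel_size = 0.1)
  expect_equal(nrow(locs), 1)
  expect_lt(abs(locs$x_px - 25.30), 0.1)
  expect_lt(abs(locs$y_px - 30.70), 0.1)

  # brute-force grid-search oracle: best (x0, y0) on a fine grid with
  # amp/bg solved by linear least squares at fixed sigma
  win <- 3
  cx <- cands$x_px[1]
  cy <- cands$y_px[1]
  rows <- (cy - win):(cy + win) + 1
  cols <- (cx - win):(cx + win) + 1
  z <- as.numeric(frame[rows, cols])
  px <- rep((cx - win):(cx + win), each = 2 * win + 1)
  py <- rep((cy - win):(cy + win), times = 2 * win + 1)
  grid <- expand.grid(
    x = seq(cx - 1, cx + 1, by = 0.02),
    y = seq(cy - 1, cy + 1, by = 0.02)
  )
  sse <- vapply(seq_len(nrow(grid)), function(g) {
    e <- exp(-((px - grid$x[g])^2 + (py - grid$y[g])^2) / (2 * 1.1^2))
    fit <- lm.fit(cbind(1, e), z)
    sum(fit$residuals^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_lt(abs(locs$x_px - best$x), 0.05)
  expect_lt(abs(locs$y_px - best$y), 0.05)
})

test_that("a symmetric spot on a pixel centre fits with zero offset", {
  frame <- spot_frame(31, 31, x0 = 15, y0 = 15, amp = 100, sigma = 1.2, bg = 5)
  locs <- refine_subpixel(
    frame, tibble::tibble(x_px = 15L, y_px = 15L, quality = 1),
    detection_config(log_sigma = 1.2), 0.1
  )
  expect_equal(locs$x_px, 15, tolerance = 1e-6)
  expect_equal(locs$y_px, 15, tolerance = 1e-6)
})

test_that("detection quality on rendered frames meets recall/precision/RMSE targets", {
  # well-separated static emitters at SNR >= 8
  cfg <- sim_config(
    n_frames = 25, image_size = c(96, 96), photons_per_frame = 700,
    background = 10, read_noise = 1, seed = 51
  )
  grid <- tidyr::crossing(gx = 1:5, gy = 1:5) |>
    dplyr::mutate(
      x_um = gx * 1.55 + 0.35 * sin(gx * 2 + gy),
      y_um = gy * 1.55 + 0.35 * cos(gx - gy * 3)
    )
  truth <- static_spot_truth(grid, cfg)
  movie <- render_movie(truth, cfg)
  sigma_px <- psf_sigma_px(cfg)
  # matched-filter threshold: a quarter of a clean spot's peak LoG response
  clean_cfg <- cfg
  clean_cfg$background <- 0
  clean_cfg$read_noise <- 0
  clean <- max_projection(render_movie(
    static_spot_truth(tibble::tibble(x_um = 4.75, y_um = 4.75), clean_cfg),
    clean_cfg,
    seed = 1
  ))
  thr <- 0.25 * max(log_filter(clean, sigma_px))
  dcfg <- detection_config(log_sigma = sigma_px, quality_threshold = thr)

  tp <- 0
  fp <- 0
  fn <- 0
  errs <- c()
  for (t in seq_len(dim(movie)[3])) {
    locs <- refine_subpixel(
      unclass(movie)[, , t],
      detect_spots(unclass(movie)[, , t], dcfg), dcfg, cfg$pixel_size
    )
    d <- outer(locs$x_px, grid$x_um / cfg$pixel_size, "-")^2 +
      outer(locs$y_px, grid$y_um / cfg$pixel_size, "-")^2
    if (nrow(locs) > 0) {
      match <- apply(d, 1, which.min)
      dist <- sqrt(d[cbind(seq_len(nrow(locs)), match)])
      hit <- dist < 1.5
      tp <- tp + length(unique(match[hit]))
      fp <- fp + sum(!hit) + (sum(hit) - length(unique(match[hit])))
      fn <- fn + nrow(grid) - length(unique(match[hit]))
      errs <- c(errs, dist[hit])
    } else {
      fn <- fn + nrow(grid)
    }
  }
  expect_gte(tp / (tp + fn), 0.95) # recall
  expect_gte(tp / (tp + fp), 0.95) # precision
  expect_lte(sqrt(mean(errs^2)), 0.3) # localization RMSE, px
})

test_that("precision and PSF summaries follow their definitions", {
  locs <- tibble::tibble(
    sigma_px = c(1.0863, 1.0863), precision_nm = c(10, 20)
  )
  s <- estimate_localization_stats(locs, pixel_size = 0.1)
  expect_equal(s$precision_mean_nm, 15)
  expect_equal(s$precision_sd_nm, sd(c(10, 20)))
  expect_equal(s$psf_half_width_mean_nm, 1.0863 * sqrt(2 * log(2)) * 100,
    tolerance = 1e-6
  )
  expect_equal(s$psf_half_width_sd_nm, 0)
  expect_error(
    estimate_localization_stats(locs[0, ]),
    "no localizations"
  )
})

test_that("simulator defaults reproduce the target localization precision", {
  cfg <- sim_config(
    n_frames = 80, image_size = c(64, 64), n_molecules = 2000,
    conversion_rate = 5e-4, seed = 3
  )
  sim <- simulate_movie(cfg)
  locs <- localize_movie(sim$movie)
  expect_gt(nrow(locs), 200)
  s <- estimate_localization_stats(locs)
  expect_gte(s$precision_mean_nm, 15)
  expect_lte(s$precision_mean_nm, 21)
  expect_lt(abs(s$psf_half_width_mean_nm - 127.9) / 127.9, 0.05)
})
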