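# Track filtering, MSD, diffusion fitting and the mobile/immobile split.

mk_tracks <- function(lengths) {
  dplyr::bind_rows(purrr::imap(lengths, function(len, id) {
    tibble::tibble(
      track_id = id, frame = seq_len(len),
      x_um = seq_len(len) * 0.01, y_um = 0
    )
  }))
}

test_that("track filter keeps 6..1000 spots and counts removals", {
  tracks <- mk_tracks(c(3, 6, 8, 1000, 1001))
  kept <- filter_tracks(tracks)
  lens <- dplyr::count(kept, track_id)
  expect_setequal(lens$n, c(6, 8, 1000))
  expect_equal(attr(kept, "n_removed_short"), 1)
  expect_equal(attr(kept, "n_removed_long"), 1)

  expect_equal(nrow(filter_tracks(mk_tracks(8)[0, ])), 0)
  all8 <- filter_tracks(mk_tracks(rep(8, 5)))
  expect_equal(dplyr::n_distinct(all8$track_id), 5)
})

test_that("MSD matches hand-computed examples", {
  stationary <- tibble::tibble(x_um = rep(2, 10), y_um = rep(-1, 10))
  expect_true(all(compute_msd(stationary, 0.03, 5)$msd == 0))

  trk <- tibble::tibble(x_um = c(0, 1, 2), y_um = c(0, 0, 0))
  curve <- compute_msd(trk, 0.03, 2)
  expect_equal(curve$msd, c(1, 4))
  expect_equal(curve$lag, c(0.03, 0.06))
  expect_equal(curve$n_pairs, c(2, 1))

  diag8 <- tibble::tibble(x_um = 0:7, y_um = 0:7)
  curve <- compute_msd(diag8, 0.03, 4)
  expect_equal(curve$msd, 2 * (1:4)^2)

  expect_error(compute_msd(trk, 0.03, 3), "n_max")
})

test_that("MSD equals the double-loop oracle on random tracks", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    x <- cumsum(rnorm(n))
    y <- cumsum(rnorm(n))
    n_max <- sample(1:(n - 1), 1)
    got <- compute_msd(tibble::tibble(x_um = x, y_um = y), 0.03, n_max)
    expect_equal(got$msd, msd_oracle(x, y, 0.03, n_max), tolerance = 1e-12)
  }
})

test_that("MSD is invariant to translation and rotation of the track", {
  set.seed(72)
  x <- cumsum(rnorm(20))
  y <- cumsum(rnorm(20))
  base <- compute_msd(tibble::tibble(x_um = x, y_um = y), 0.03, 8)$msd
  shifted <- compute_msd(
    tibble::tibble(x_um = x + 5, y_um = y - 3), 0.03, 8
  )$msd
  th <- 0.7
  rotated <- compute_msd(
    tibble::tibble(
      x_um = x * cos(th) - y * sin(th),
      y_um = x * sin(th) + y * cos(th)
    ),
    0.03, 8
  )$msd
  expect_equal(base, shifted, tolerance = 1e-12)
  expect_equal(base, rotated, tolerance = 1e-12)
})

test_that("ensemble MSD averages across tracks with sample SD", {
  per_track <- dplyr::bind_rows(
    tibble::tibble(track_id = 1, lag = c(0.03, 0.06), msd = c(1, 2), n_pairs = c(9, 8)),
    tibble::tibble(track_id = 2, lag = c(0.03, 0.06), msd = c(3, 4), n_pairs = c(5, 4))
  )
  ens <- ensemble_msd(per_track)
  expect_equal(ens$msd, c(2, 3))
  expect_equal(ens$sd, c(sqrt(2), sqrt(2)))
  expect_equal(ens$n_tracks, c(2L, 2L))

  same <- ensemble_msd(dplyr::mutate(per_track, msd = c(1, 2, 1, 2)))
  expect_equal(same$msd, c(1, 2))
  expect_equal(same$sd, c(0, 0))
})

test_that("tracks shorter than a lag drop out of that lag only", {
  tracks <- mk_tracks(c(6, 12))
  per_track <- track_msds(tracks, frame_interval = 0.03, n_max = 10)
  ens <- ensemble_msd(per_track)
  expect_equal(ens$n_tracks[1:5], rep(2L, 5))
  expect_equal(ens$n_tracks[6:10], rep(1L, 5))
})

test_that("diffusion fit recovers exact linear and affine inputs", {
  lags <- 0.03 * (1:6)
  pure <- tibble::tibble(lag = lags, msd = 4 * 0.05 * lags)
  f <- fit_diffusion(pure)
  expect_equal(f$D, 0.05, tolerance = 1e-12)
  expect_equal(f$alpha, 0, tolerance = 1e-12)

  offset <- tibble::tibble(lag = lags, msd = 0.01 + 4 * 0.1 * lags)
  f2 <- fit_diffusion(offset)
  expect_equal(f2$D, 0.1, tolerance = 1e-12)
  expect_equal(f2$alpha, 0.01, tolerance = 1e-12)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_diffusion(pure[1:3, ]), "four")
})

test_that("the 4-point fit matches the closed-form OLS oracle and uses only 4 points", {
  set.seed(73)
  lags <- 0.03 * (1:10)
  msd <- 0.005 + 0.4 * lags + rnorm(10, 0, 0.003)
  f <- fit_diffusion(tibble::tibble(lag = lags, msd = msd))
  o <- ols_oracle(lags[1:4], msd[1:4])
  expect_equal(f$alpha, unname(o["intercept"]), tolerance = 1e-10)
  expect_equal(f$D, unname(o["slope"]) / 4, tolerance = 1e-10)
  # points beyond the fourth lag must not influence the fit
  msd2 <- msd
  msd2[5:10] <- msd2[5:10] + 1
  f2 <- fit_diffusion(tibble::tibble(lag = lags, msd = msd2))
  expect_equal(f2$D, f$D)
})

test_that("tidy and glance expose the diffusion fit like a model object", {
  f <- fit_diffusion(tibble::tibble(lag = 0.03 * (1:4), msd = 0.01 + 0.12 * (1:4)))
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "D"))
  g <- glance(f)
  expect_named(g, c("D", "alpha", "r.squared", "n_points"))
  expect_equal(g$D, f$D)
})

test_that("diffusion recovery from simulated noisy tracks is unbiased", {
  cfg <- sim_config(
    n_frames = 150, image_size = c(256, 256), n_molecules = 8000,
    conversion_rate = 0.01, bleach_rate = 0.1, blink_off_rate = 0,
    D_populations = tibble::tibble(D = 0.1, fraction = 1), seed = 74
  )
  truth <- simulate_trajectories(cfg)
  # sigma_loc = 0: D within Monte-Carlo error of truth, alpha near 0
  clean <- filter_tracks(truth_tracks(truth, sigma_loc = 0))
  ens <- ensemble_msd(track_msds(clean, 0.03, 10))
  f0 <- fit_diffusion(ens)
  expect_lt(abs(f0$D - 0.1) / 0.1, 0.1)
  expect_lt(abs(f0$alpha), 1e-3)
  # sigma_loc = 18 nm: alpha approx 4 sigma^2 = 0.0013 um^2
  noisy <- filter_tracks(truth_tracks(truth, sigma_loc = 0.018))
  f1 <- fit_diffusion(ensemble_msd(track_msds(noisy, 0.03, 10)))
  expect_lt(abs(f1$alpha - 0.0013) / 0.0013, 0.5)
})

test_that("mobility ratio splits tracks at log10 D = -1.6", {
  r <- mobility_ratio(10^c(-1, -1, -2, -2))
  expect_equal(r$mobile_fraction, 0.5)
  expect_equal(r$ratio, 1)

  r2 <- mobility_ratio(c(0.1, 0.01, 0.001))
  expect_equal(r2$mobile_fraction, 1 / 3)
  expect_equal(r2$immobile_fraction, 2 / 3)
  expect_equal(r2$ratio, 0.5)

  r3 <- mobility_ratio(rep(1e-3, 4))
  expect_false(r3$ratio_defined)
  expect_true(is.na(r3$ratio))

  r4 <- mobility_ratio(c(-0.01, 0.1, 0.2))
  expect_equal(r4$n_excluded, 1)
  expect_equal(
    r4$mobile_fraction + r4$immobile_fraction, 1
  )
  expect_error(mobility_ratio(c(-1, 0)), "positive")
})
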