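# Paired normalization, AUC, delta mobility, drift QC and statistics.

mk_curve <- function(msd, lags = 0.03 * seq_along(msd)) {
  tibble::tibble(lag = lags, msd = msd)
}

test_that("normalization divides both curves by the baseline peak scalar", {
  set.seed(81)
  for (i in 1:10) {
    base <- mk_curve(cumsum(runif(10, 0.01, 0.05)))
    trt <- mk_curve(cumsum(runif(10, 0.01, 0.08)))
    pair <- normalize_to_baseline(paired_recording(base, trt))
    expect_true(pair$normalized_baseline$msd[10] == 1)
    expect_equal(
      pair$normalized_treatment$msd,
      trt$msd / base$msd[10]
    )
  }

  base <- mk_curve(seq(0.01, 0.1, length.out = 10))
  ident <- normalize_to_baseline(paired_recording(base, base))
  expect_equal(ident$normalized_treatment$msd[10], 1)
  doubled <- normalize_to_baseline(
    paired_recording(base, mk_curve(2 * base$msd))
  )
  expect_equal(doubled$normalized_treatment$msd[10], 2)

  expect_error(
    normalize_to_baseline(paired_recording(mk_curve(rep(0, 10)), base)),
    "positive"
  )
  expect_error(
    paired_recording(base, mk_curve(base$msd, lags = base$lag + 0.01)),
    "lag grid"
  )
})

test_that("AUC reproduces hand-computed trapezoid areas", {
  expect_equal(compute_auc(mk_curve(rep(0, 10))), 0)
  tri <- tibble::tibble(lag = c(0, 0.1, 0.2, 0.3), msd = c(0, 0.1, 0.2, 0.3))
  expect_equal(compute_auc(tri), 0.045)
  flat <- tibble::tibble(lag = 0.03 * (1:10), msd = rep(1, 10))
  expect_equal(compute_auc(flat), 0.27)
  expect_error(compute_auc(tri[1, ]), "two")
})

test_that("AUC is linear in the curve and ignores sub-10% stray peaks", {
  set.seed(82)
  y <- cumsum(runif(10, 0, 0.1))
  curve <- mk_curve(y)
  expect_equal(compute_auc(dplyr::mutate(curve, msd = 3 * msd)),
    3 * compute_auc(curve),
    tolerance = 1e-12
  )
  # a small isolated bump (3% of the range) between negative flanks is
  # excluded; the main region is kept
  wig <- tibble::tibble(
    lag = seq(0, 0.9, by = 0.1),
    msd = c(-0.2, 0.03, -0.2, 0, 1, 2, 3, 2.5, 2, 1)
  )
  with_bump <- compute_auc(wig)
  no_bump <- compute_auc(dplyr::mutate(wig, msd = replace(msd, 2, -0.2)))
  expect_equal(with_bump, no_bump)
})

test_that("delta mobility is the normalized treatment peak minus 1", {
  base <- mk_curve(seq(0.02, 0.2, length.out = 10))
  same <- compare_pair(paired_recording(base, base))
  expect_equal(same$delta, 0)
  up <- compare_pair(paired_recording(base, mk_curve(1.3 * base$msd)))
  expect_equal(up$delta, 0.3, tolerance = 1e-12)
  down <- compare_pair(paired_recording(base, mk_curve(0.9 * base$msd)))
  expect_equal(down$delta, -0.1, tolerance = 1e-12)
  g <- glance(up)
  expect_equal(g$delta, up$delta)
  expect_gt(g$auc_treatment, g$auc_baseline)
})

test_that("drift Pearson r has the defining limits and affine invariance", {
  set.seed(83)
  img <- matrix(runif(400), 20, 20)
  expect_equal(drift_pearson(img, img), 1)
  expect_equal(drift_pearson(img, max(img) - img), -1)
  expect_equal(drift_pearson(img, 3 * img + 7), 1)
  other <- matrix(runif(400), 20, 20)
  r <- drift_pearson(img, other)
  expect_true(r >= -1 && r <= 1)
  expect_equal(drift_pearson(img, 2 * other - 1), r, tolerance = 1e-12)
  expect_error(drift_pearson(img, matrix(1, 20, 20)), "constant")
  expect_error(drift_pearson(img, matrix(1, 10, 10)), "dimensions")
})

test_that("drift regression matches the closed-form OLS oracle", {
  col <- tibble::tibble(pearson_r = c(0.1, 0.5, 0.9), delta = c(1, 3, 5))
  f <- drift_regression(col)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$slope, 5)

  set.seed(84)
  df <- tibble::tibble(pearson_r = runif(40), delta = rnorm(40))
  fit <- drift_regression(df)
  o <- ols_oracle(df$pearson_r, df$delta)
  expect_equal(fit$slope, unname(o["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-10)
  expect_lt(abs(fit$slope), 1) # y independent of x
  expect_lt(fit$r_squared, 0.2)
  expect_named(glance(fit), c("slope", "intercept", "r.squared", "p.value", "n"))
})

test_that("paired Wilcoxon p equals exhaustive sign enumeration at n = 6", {
  base <- c(1.0, 1.1, 0.9, 1.05, 1.2, 0.95)
  trt <- base + c(0.21, 0.13, -0.07, 0.17, 0.11, 0.23)
  got <- paired_test(base, trt)
  expect_equal(got$p_value, wilcoxon_exact_oracle(trt - base),
    tolerance = 1e-12
  )

  degenerate <- paired_test(base, base)
  expect_false(degenerate$defined)
  expect_true(is.na(degenerate$p_value))
})

test_that("group tests select KS / Mann-Whitney / Kruskal-Wallis appropriately", {
  set.seed(85)
  a <- rnorm(20)
  same <- group_test(list(a = a, b = a))
  expect_equal(same$method, "Kolmogorov-Smirnov")
  expect_gt(same$p_value, 0.99)

  b <- rnorm(15, 1)
  ks <- group_test(list(a = a, b = b))
  expect_equal(unname(ks$statistic), ks_d_oracle(a, b), tolerance = 1e-12)
  mw <- group_test(list(a = a, b = b), two_group_test = "mw")
  expect_equal(mw$method, "Mann-Whitney")

  shifted <- rnorm(20, 3)
  kw <- group_test(list(rnorm(20), rnorm(20), shifted))
  expect_equal(kw$method, "Kruskal-Wallis")
  expect_lt(kw$p_value, 0.01)

  expect_error(group_test(list(a, 1:2)), "three")
})

test_that("doubling D raises the normalized treatment curve; immobilization lowers it", {
  cfg <- sim_config(
    n_frames = 120, image_size = c(128, 128), n_molecules = 3000,
    conversion_rate = 0.005, seed = 86
  )
  pr <- simulate_paired_recording(cfg, stim_factor = 2, render = FALSE)
  ens <- function(truth) {
    ensemble_msd(track_msds(filter_tracks(truth_tracks(truth)), 0.03, 10))
  }
  stim <- compare_pair(paired_recording(ens(pr$baseline$truth), ens(pr$treatment$truth)))
  expect_gt(stim$delta, 0)
  expect_gt(stim$auc_treatment, stim$auc_baseline)

  anes <- simulate_paired_recording(
    cfg,
    treatment_D_populations = tibble::tibble(
      D = c(0.1, 0.001), fraction = c(0.4, 0.6)
    ),
    render = FALSE
  )
  sedated <- compare_pair(paired_recording(
    ens(anes$baseline$truth), ens(anes$treatment$truth)
  ))
  expect_lt(sedated$delta, 0)
  expect_lt(sedated$auc_treatment, sedated$auc_baseline)
})
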