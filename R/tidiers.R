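# broom-style tidiers for the fitted objects.

#' Tidy a diffusion fit
#'
#' @param x An `spt_dfit` from [fit_diffusion()].
#' @param ... Unused.
#' @return Tibble with one row per model term (alpha, D) with estimate and
#'   standard error.
#' @export
#' @exportS3Method generics::tidy
tidy.spt_dfit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("alpha", "D"),
    estimate = c(x$alpha, x$D),
    std.error = c(sm[1, 2], sm[2, 2] / 4),
    statistic = sm[, 3],
    p.value = sm[, 4]
  )
}

#' @rdname tidy.spt_dfit
#' @export
#' @exportS3Method generics::glance
glance.spt_dfit <- function(x, ...) {
  tibble::tibble(
    D = x$D, alpha = x$alpha, r.squared = x$r_squared,
    n_points = x$n_points
  )
}

#' Tidy the drift regression
#'
#' @param x An `spt_drift_fit` from [drift_regression()].
#' @param ... Unused.
#' @return Term-level (tidy) or model-level (glance) tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.spt_drift_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    statistic = sm[, 3],
    p.value = sm[, 4]
  )
}

#' @rdname tidy.spt_drift_fit
#' @export
#' @exportS3Method generics::glance
glance.spt_drift_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    r.squared = x$r_squared, p.value = x$p_value, n = x$n
  )
}

#' One-row summary of a paired comparison
#'
#' @param x An `spt_comparison` from [compare_pair()].
#' @param ... Unused.
#' @return Tibble: auc_baseline, auc_treatment, delta, pearson_r,
#'   peak_lag.
#' @export
#' @exportS3Method generics::glance
glance.spt_comparison <- function(x, ...) {
  tibble::tibble(
    auc_baseline = x$auc_baseline,
    auc_treatment = x$auc_treatment,
    delta = x$delta,
    pearson_r = x$pearson_r,
    peak_lag = x$peak_lag
  )
}
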