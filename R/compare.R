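# Internally controlled paired analysis: baseline-peak normalization of
# MSD curves, area under the normalized curve, delta mobility at the peak
# lag, maximum-projection Pearson drift QC, and nonparametric statistics.

#' Bundle a paired (baseline/treatment) recording
#'
#' @param baseline_curve,treatment_curve Ensemble `spt_msd` curves on the
#'   same lag grid (baseline = unstimulated/control recording, treatment =
#'   the second recording of the same field).
#' @param baseline_maxproj,treatment_maxproj Optional maximum-projection
#'   images for drift QC.
#' @return List of class `paired_recording`.
#' @export
paired_recording <- function(baseline_curve, treatment_curve,
                             baseline_maxproj = NULL,
                             treatment_maxproj = NULL) {
  stopifnot(
    all(c("lag", "msd") %in% names(baseline_curve)),
    all(c("lag", "msd") %in% names(treatment_curve))
  )
  if (!isTRUE(all.equal(baseline_curve$lag, treatment_curve$lag))) {
    stop("baseline and treatment curves must share the same lag grid",
      call. = FALSE
    )
  }
  structure(
    list(
      baseline_curve = baseline_curve,
      treatment_curve = treatment_curve,
      baseline_maxproj = baseline_maxproj,
      treatment_maxproj = treatment_maxproj
    ),
    class = "paired_recording"
  )
}

# value of a curve at a lag (exact grid match within tolerance)
curve_at_lag <- function(curve, lag) {
  i <- which(abs(curve$lag - lag) < 1e-9)
  if (length(i) != 1) {
    stop("lag ", lag, " s is not on the curve's lag grid", call. = FALSE)
  }
  curve$msd[i]
}

#' Normalize a paired recording to the baseline peak
#'
#' Both curves are divided by one scalar: the baseline curve's value at
#' the peak lag (0.30 s by default), so the normalized baseline peak is
#' exactly 1.0. With `peak = "max"` the baseline maximum over lags is used
#' instead, for non-monotone curves.
#'
#' @param pair A [paired_recording()].
#' @param peak_lag Peak lag in seconds (default 0.30).
#' @param peak `"at_lag"` (default) or `"max"`.
#' @return The pair with `normalized_baseline` and `normalized_treatment`
#'   curves (unitless `msd` column) and `peak_lag`, `divisor` fields
#'   added.
#' @export
normalize_to_baseline <- function(pair, peak_lag = 0.30,
                                  peak = c("at_lag", "max")) {
  stopifnot(inherits(pair, "paired_recording"))
  peak <- match.arg(peak)
  divisor <- if (peak == "at_lag") {
    curve_at_lag(pair$baseline_curve, peak_lag)
  } else {
    max(pair$baseline_curve$msd)
  }
  if (!is.finite(divisor) || divisor <= 0) {
    stop("baseline peak must be positive to normalize", call. = FALSE)
  }
  norm <- function(curve) {
    curve$msd <- curve$msd / divisor
    if ("sd" %in% names(curve)) curve$sd <- curve$sd / divisor
    curve
  }
  pair$normalized_baseline <- norm(pair$baseline_curve)
  pair$normalized_treatment <- norm(pair$treatment_curve)
  pair$peak_lag <- peak_lag
  pair$divisor <- divisor
  pair
}

#' Area under a normalized MSD curve
#'
#' Trapezoidal area above the baseline Y = 0 between the first and last
#' lag. Separate above-baseline regions whose height is less than
#' `min_peak_frac` of the curve's min-to-max range are ignored; monotone
#' MSD curves form a single region, so the rule rarely triggers but
#' mirrors the stated peak-counting convention.
#'
#' @param curve Tibble with `lag` (s) and `msd` (unitless after
#'   normalization), at least two points.
#' @param min_peak_frac Fraction of the Y range below which an isolated
#'   peak is ignored (default 0.1).
#' @return Area in unitless * s.
#' @examples
#' compute_auc(tibble::tibble(lag = c(0, 0.1, 0.2, 0.3), msd = c(0, 0.1, 0.2, 0.3)))
#' @export
compute_auc <- function(curve, min_peak_frac = 0.1) {
  stopifnot(all(c("lag", "msd") %in% names(curve)))
  if (nrow(curve) < 2) {
    stop("AUC needs at least two curve points", call. = FALSE)
  }
  curve <- dplyr::arrange(tibble::as_tibble(curve), .data$lag)
  x <- curve$lag
  y <- curve$msd
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  pos <- y > 0
  if (!any(pos)) {
    return(0)
  }
  region <- cumsum(c(pos[1], diff(pos) == 1))
  region[!pos] <- NA
  height_cut <- min_peak_frac * (max(y) - min(y))
  total <- 0
  for (rg in unique(stats::na.omit(region))) {
    idx <- which(!is.na(region) & region == rg)
    if (max(y[idx]) < height_cut) next # peak too small: ignored
    a <- 0
    for (i in idx) {
      # right edge toward i+1
      if (i < length(y)) {
        if (y[i + 1] > 0) {
          if ((i + 1) %in% idx) a <- a + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
        } else {
          xc <- x[i] + (x[i + 1] - x[i]) * y[i] / (y[i] - y[i + 1])
          a <- a + (xc - x[i]) * y[i] / 2
        }
      }
      # left edge from a non-positive neighbour (zero crossing)
      if (i > 1 && y[i - 1] <= 0 && y[i - 1] < y[i]) {
        xc <- x[i] - (x[i] - x[i - 1]) * y[i] / (y[i] - y[i - 1])
        a <- a + (x[i] - xc) * y[i] / 2
      }
    }
    total <- total + a
  }
  total
}

#' Delta mobility of a normalized pair
#'
#' The normalized treatment value at the peak lag minus the normalized
#' baseline value there; since the baseline peak is 1 by construction,
#' this is the treatment peak minus 1. Positive values mean increased
#' mobility (stimulation), negative values decreased mobility
#' (immobilization).
#'
#' @param pair A pair that has been through [normalize_to_baseline()].
#' @return Numeric delta mobility.
#' @export
delta_mobility <- function(pair) {
  stopifnot(inherits(pair, "paired_recording"))
  if (is.null(pair$normalized_baseline)) {
    stop("normalize the pair with normalize_to_baseline() first",
      call. = FALSE
    )
  }
  curve_at_lag(pair$normalized_treatment, pair$peak_lag) -
    curve_at_lag(pair$normalized_baseline, pair$peak_lag)
}

#' Pearson drift correlation between two maximum projections
#'
#' Pixel-wise Pearson product-moment correlation over all pixels of the
#' two images; sample drift between the two recordings of a field lowers
#' it.
#'
#' @param maxproj_a,maxproj_b Matrices of identical size with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
drift_pearson <- function(maxproj_a, maxproj_b) {
  stopifnot(is.matrix(maxproj_a), is.matrix(maxproj_b))
  if (!identical(dim(maxproj_a), dim(maxproj_b))) {
    stop("projections must have identical dimensions", call. = FALSE)
  }
  if (sd(maxproj_a) == 0 || sd(maxproj_b) == 0) {
    stop("constant image: Pearson correlation undefined", call. = FALSE)
  }
  cor(as.vector(maxproj_a), as.vector(maxproj_b))
}

#' Regression of delta mobility on drift correlation
#'
#' Ordinary least-squares line of delta mobility against the Pearson
#' drift coefficient across paired recordings, with R^2 and the slope
#' t-test p-value; used to show how much of the mobility response drift
#' explains.
#'
#' @param pairs Tibble/data frame with columns `pearson_r` and `delta`
#'   (at least three rows).
#' @return Object of class `spt_drift_fit` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, and the underlying `lm`.
#' @export
drift_regression <- function(pairs) {
  stopifnot(all(c("pearson_r", "delta") %in% names(pairs)))
  if (nrow(pairs) < 3) {
    stop("drift regression needs at least three pairs", call. = FALSE)
  }
  if (sd(pairs$pearson_r) == 0) {
    stop("degenerate regression: pearson_r has zero variance", call. = FALSE)
  }
  fit <- lm(delta ~ pearson_r, data = pairs)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = sm$coefficients[2, 4],
      n = nrow(pairs),
      fit = fit
    ),
    class = "spt_drift_fit"
  )
}

#' @export
print.spt_drift_fit <- function(x, ...) {
  cat(
    "delta mobility ~ Pearson r: slope = ", signif(x$slope, 4),
    ", R^2 = ", signif(x$r_squared, 4),
    ", p = ", signif(x$p_value, 3), " (n = ", x$n, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank test on paired AUCs
#'
#' Exact distribution for small samples without ties (the default
#' behaviour of [stats::wilcox.test()] below n = 50), normal approximation
#' otherwise. Zero differences are dropped, the standard signed-rank
#' convention; if every difference is zero the test is undefined and
#' flagged instead of erroring.
#'
#' @param baseline,treatment Paired numeric vectors (e.g. per-replicate
#'   AUCs).
#' @return One-row tibble: `method`, `statistic`, `p_value`, `n_pairs`,
#'   `n_used` (pairs with nonzero difference), `defined`.
#' @export
paired_test <- function(baseline, treatment) {
  stopifnot(length(baseline) == length(treatment), length(baseline) >= 1)
  diffs <- treatment - baseline
  n_used <- sum(diffs != 0)
  if (n_used == 0) {
    return(tibble::tibble(
      method = "Wilcoxon matched-pairs signed-rank",
      statistic = NA_real_, p_value = NA_real_,
      n_pairs = length(diffs), n_used = 0L, defined = FALSE
    ))
  }
  ht <- suppressWarnings(wilcox.test(treatment, baseline, paired = TRUE))
  tibble::tibble(
    method = "Wilcoxon matched-pairs signed-rank",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_pairs = length(diffs),
    n_used = n_used,
    defined = TRUE
  )
}

#' Nonparametric group comparison of AUC distributions
#'
#' Two groups: Kolmogorov-Smirnov (default, as used for
#' condition-vs-control comparisons) or Mann-Whitney. Three or more
#' groups: Kruskal-Wallis.
#'
#' @param groups Named list of numeric vectors, each with >= 3 values.
#' @param two_group_test `"ks"` (default) or `"mw"`.
#' @return One-row tibble: `method`, `statistic`, `p_value`, `n_groups`.
#' @export
group_test <- function(groups, two_group_test = c("ks", "mw")) {
  two_group_test <- match.arg(two_group_test)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop("every group needs at least three values", call. = FALSE)
  }
  if (length(groups) == 2) {
    ht <- if (two_group_test == "ks") {
      suppressWarnings(ks.test(groups[[1]], groups[[2]]))
    } else {
      suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
    }
    method <- if (two_group_test == "ks") {
      "Kolmogorov-Smirnov"
    } else {
      "Mann-Whitney"
    }
  } else {
    ht <- kruskal.test(groups)
    method <- "Kruskal-Wallis"
  }
  tibble::tibble(
    method = method,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_groups = length(groups)
  )
}

#' Full comparison of one paired recording
#'
#' Normalizes to the baseline peak, computes both AUCs, delta mobility,
#' and (when projections are present) the Pearson drift coefficient.
#'
#' @param pair A [paired_recording()].
#' @param peak_lag Peak lag (s), default 0.30.
#' @param peak Peak rule, see [normalize_to_baseline()].
#' @return Object of class `spt_comparison`: the normalized pair plus
#'   `auc_baseline`, `auc_treatment`, `delta`, `pearson_r` (NA without
#'   projections).
#' @export
compare_pair <- function(pair, peak_lag = 0.30, peak = c("at_lag", "max")) {
  pair <- normalize_to_baseline(pair, peak_lag = peak_lag, peak = peak)
  pair$auc_baseline <- compute_auc(pair$normalized_baseline)
  pair$auc_treatment <- compute_auc(pair$normalized_treatment)
  pair$delta <- delta_mobility(pair)
  pair$pearson_r <- if (!is.null(pair$baseline_maxproj) &&
    !is.null(pair$treatment_maxproj)) {
    drift_pearson(pair$baseline_maxproj, pair$treatment_maxproj)
  } else {
    NA_real_
  }
  class(pair) <- c("spt_comparison", "paired_recording")
  pair
}

#' @export
print.spt_comparison <- function(x, ...) {
  cat("sptPALM paired comparison (peak lag ", x$peak_lag, " s)\n",
    "  AUC baseline:  ", signif(x$auc_baseline, 4), "\n",
    "  AUC treatment: ", signif(x$auc_treatment, 4), "\n",
    "  delta mobility: ", signif(x$delta, 4), "\n",
    "  drift Pearson r: ", signif(x$pearson_r, 4), "\n",
    sep = ""
  )
  invisible(x)
}
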