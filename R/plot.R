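# ggplot2 visualisations for MSD curves, comparisons, and diffusion
# histograms.

#' Plot an MSD curve
#'
#' Ensemble curves get a +/- SD ribbon when the `sd` column is present.
#'
#' @param object An `spt_msd` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.spt_msd <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$msd))
  if ("sd" %in% names(object) && any(is.finite(object$sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$msd - .data$sd,
        ymax = .data$msd + .data$sd
      ),
      alpha = 0.2
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "lag time (s)",
      y = expression(MSD ~ (mu * m^2))
    ) +
    ggplot2::theme_classic()
}

#' Plot a normalized paired comparison
#'
#' Baseline and treatment normalized MSD curves with the baseline peak at
#' 1 marked.
#'
#' @param object An `spt_comparison` from [compare_pair()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.spt_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$normalized_baseline),
      condition = "baseline"
    ),
    dplyr::mutate(tibble::as_tibble(object$normalized_treatment),
      condition = "treatment"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$lag, y = .data$msd,
    colour = .data$condition
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag time (s)", y = "normalized MSD") +
    ggplot2::theme_classic()
}

#' Histogram of per-track log10 diffusion coefficients
#'
#' Fixed 0.2-wide bins over log10(D) in [-5, 1] with the mobile/immobile
#' threshold marked; tracks with D <= 0 are omitted.
#'
#' @param diffusion Tibble from [track_diffusion()] (or numeric D vector).
#' @param log10_threshold Mobility cutoff (default -1.6).
#' @return A ggplot.
#' @export
plot_diffusion_histogram <- function(diffusion, log10_threshold = -1.6) {
  D <- if (is.data.frame(diffusion)) diffusion$D else diffusion
  df <- tibble::tibble(log10_D = log10(D[D > 0 & is.finite(D)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_D)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$count / sum(.data$count))),
      breaks = seq(-5, 1, by = 0.2),
      fill = "grey70", colour = "grey30"
    ) +
    ggplot2::geom_vline(
      xintercept = log10_threshold, linetype = "dashed",
      colour = "red"
    ) +
    ggplot2::labs(
      x = expression(log[10] ~ D ~ (mu * m^2 / s)),
      y = "relative frequency"
    ) +
    ggplot2::theme_classic()
}
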