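#' QQ plot of p-values with a simultaneous ELL acceptance band
#'
#' Uniform QQ plot on the -log10 scale with the equal-local-levels
#' simultaneous acceptance band of [qq_acceptance_band()]. With many
#' p-values the band (quadratic-cost to calibrate) is computed on a
#' thinned set of ranks.
#'
#' @param pvalues numeric vector.
#' @param level simultaneous band non-coverage.
#' @param band_n calibrate the band at this many p-values at most; the
#'   observed vector is subsampled (evenly on ranks) beyond it.
#' @return a ggplot object.
#' @export
plot_qq <- function(pvalues, level = 0.05, band_n = 200L) {
  n <- length(pvalues)
  if (n > band_n) {
    keep <- unique(round(seq(1L, n, length.out = band_n)))
    ps <- sort(pvalues)[keep]
  } else {
    ps <- sort(pvalues)
  }
  band <- qq_acceptance_band(length(ps), level = level)
  df <- dplyr::mutate(band, observed = ps)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$expected))) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = -log10(.data$upper), ymax = -log10(pmax(.data$lower, 1e-300))),
      fill = "grey85"
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = -log10(.data$observed)), size = 0.8) +
    ggplot2::labs(
      x = expression(-log[10] * " expected p"),
      y = expression(-log[10] * " observed p")
    ) +
    ggplot2::theme_minimal()
}

#' Relative-power profile across sparsity settings
#'
#' @param power_tbl tibble from [run_power_study()].
#' @return a ggplot object: relative power (power / per-setting maximum)
#'   against the number of associated traits, one line per method.
#' @export
plot_relative_power <- function(power_tbl) {
  ggplot2::ggplot(
    power_tbl,
    ggplot2::aes(x = .data$A, y = .data$relative_power,
                 colour = .data$method, group = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "associated traits (A)", y = "relative power") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.adelle_scan <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$method == .data$method[1L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$chrom),
                                     shape = .data$discovery)) +
    ggplot2::labs(x = "SNP", y = expression(-log[10] * " global p"),
                  colour = "chromosome", shape = "FDR discovery") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
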