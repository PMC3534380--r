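# ggplot2 figures for the pipeline's result objects.

#' Coverage depth histogram with matched-mean Poisson reference
#'
#' The observed fraction of non-N bases at each depth (bars) against the
#' Poisson probability mass function with the same mean (line); an
#' overdispersed library shows more weight in both tails than the line.
#'
#' @param profile A `coverage_profile`.
#' @return A ggplot object.
#' @export
plot_coverage <- function(profile) {
  df <- tidy(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fraction), fill = "grey35",
                      width = 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$poisson_pmf),
                       colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(
      x = "Depth of coverage",
      y = "Fraction of non-N bases",
      title = sprintf("Coverage depth distribution (mean %.2f)",
                      profile$mean_depth),
      subtitle = "Line: Poisson with matched mean"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coverage_profile <- function(object, ...) plot_coverage(object)

#' GC content versus mean depth in fixed windows
#'
#' @param profile A `coverage_profile`.
#' @return A ggplot object.
#' @export
plot_gc_depth <- function(profile) {
  ggplot2::ggplot(profile$windows,
                  ggplot2::aes(x = 100 * .data$gc, y = .data$mean_depth)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "GC (%)", y = "Mean depth",
                  title = "Window GC vs coverage") +
    ggplot2::theme_minimal()
}

#' Variant density around transcription start sites
#'
#' @param profile A `tss_profile` tibble.
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin_mid,
                               y = .data$mean_per_transcript)) +
    ggplot2::geom_col(width = diff(profile$bin_start[1:2]) * 0.9,
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Position relative to TSS (bp, transcript orientation)",
      y = "Mean variants per transcript",
      title = "Variant density around TSS"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tss_profile <- function(object, ...) plot_tss_profile(object)

#' RiskOgram: cumulative post-test probability as SNPs are incorporated
#'
#' SNPs appear in decreasing order of supporting studies; the curve shows
#' the post-test probability after each, starting from the pre-test
#' probability (dashed line).
#'
#' @param rog A `riskogram` tibble (or a `risk_assessment`).
#' @return A ggplot object.
#' @export
plot_riskogram <- function(rog) {
  if (inherits(rog, "risk_assessment")) rog <- rog$riskogram
  p0 <- attr(rog, "p0")
  df <- as_tibble(rog) %>% mutate(step = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step,
                                   y = .data$cumulative_posttest)) +
    ggplot2::geom_hline(yintercept = p0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(size = log10(.data$n_samples)),
                        alpha = 0.7) +
    ggplot2::scale_x_continuous(breaks = df$step, labels = df$rsid) +
    ggplot2::scale_size_continuous(name = "log10 samples") +
    ggplot2::labs(
      x = "SNP (decreasing number of supporting studies)",
      y = "Post-test probability",
      title = "Cumulative disease risk"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.riskogram <- function(object, ...) plot_riskogram(object)
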