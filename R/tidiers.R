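# broom-style tidiers for the pipeline's result objects.

#' Tidy a filter report into per-rule counts
#' @param x A `filter_report`.
#' @param ... Unused.
#' @return Tibble (rule, n).
#' @export
tidy.filter_report <- function(x, ...) {
  tibble(
    rule = c("input", "pass", "fail_depth", "fail_quality",
             "fail_het_no_ref"),
    n = c(x$n_input, x$n_pass, x$n_fail_depth, x$n_fail_quality,
          x$n_fail_het_no_ref)
  )
}

#' One-row summary of a filter report
#' @param x A `filter_report`.
#' @param ... Unused.
#' @return One-row tibble with counts and the pass rate.
#' @export
glance.filter_report <- function(x, ...) {
  tibble(
    n_input = x$n_input, n_pass = x$n_pass,
    n_fail_depth = x$n_fail_depth, n_fail_quality = x$n_fail_quality,
    n_fail_het_no_ref = x$n_fail_het_no_ref,
    pass_rate = if (x$n_input > 0) x$n_pass / x$n_input else NA_real_
  )
}

#' Tidy a coverage profile: histogram with its Poisson reference
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @return Tibble (depth, fraction, poisson_pmf).
#' @export
tidy.coverage_profile <- function(x, ...) {
  full_join(x$histogram, x$poisson_ref, by = "depth") %>%
    mutate(fraction = dplyr::coalesce(.data$fraction, 0)) %>%
    rename(poisson_pmf = "pmf") %>%
    arrange(.data$depth)
}

#' One-row summary of a coverage profile
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @return One-row tibble (mean_depth, frac_ge1, frac_ge5, n_windows).
#' @export
glance.coverage_profile <- function(x, ...) {
  tibble(
    mean_depth = x$mean_depth,
    frac_ge1 = x$frac_ge1,
    frac_ge5 = x$frac_ge5,
    n_windows = nrow(x$windows)
  )
}

#' @importFrom dplyr full_join
NULL

#' Tidy a risk assessment into its RiskOgram steps
#' @param x A `risk_assessment`.
#' @param ... Unused.
#' @return Tibble, one row per cumulative step (rsid, n_studies, n_samples,
#'   genotype, lr, cumulative_lr, cumulative_posttest).
#' @export
tidy.risk_assessment <- function(x, ...) {
  as_tibble(x$riskogram) %>%
    select("rsid", "n_studies", "n_samples", "genotype", "lr",
           "cumulative_lr", "cumulative_posttest")
}

#' One-row summary of a risk assessment
#' @param x A `risk_assessment`.
#' @param ... Unused.
#' @return One-row tibble (disease, pretest, n_kept, combined_lr, posttest,
#'   percentile).
#' @export
glance.risk_assessment <- function(x, ...) {
  tibble(
    disease = x$disease,
    pretest = x$pretest,
    n_kept = dplyr::n_distinct(x$kept$rsid),
    combined_lr = x$combined_lr,
    posttest = x$posttest,
    percentile = x$percentile
  )
}
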