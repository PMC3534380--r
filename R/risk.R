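# Likelihood-ratio disease-risk engine: pre-test probability lookup, greedy
# LD pruning, LR combination on the odds scale, population percentile,
# RiskOgram series and pharmacogenomic lookup.
#
# The model: with pre-test probability p0 and genotype likelihood ratios
# LR_i = P(g_i | disease) / P(g_i | no disease) at SNPs independent given
# disease status, the post-test odds are odds(p0) * prod(LR_i), hence
# p1 = Lambda * p0 / (1 - p0) / (1 + Lambda * p0 / (1 - p0)).

#' Look up the pre-test probability for a demographic stratum
#'
#' Exact-stratum lookup: the disease, sex and ethnicity must match and the
#' age must fall in the stratum's `[age_lo, age_hi]`. No match, or more than
#' one, is an error (the available strata are listed).
#'
#' @param table Prevalence tibble (disease, age_lo, age_hi, sex, ethnicity,
#'   pretest_prob).
#' @param disease,age,sex,ethnicity Query stratum.
#' @return The pre-test probability (scalar in (0,1)).
#' @export
pretest_probability <- function(table, disease, age, sex, ethnicity) {
  m <- table %>%
    filter(.data$disease == !!disease, .data$sex == !!sex,
           .data$ethnicity == !!ethnicity,
           .data$age_lo <= !!age, .data$age_hi >= !!age)
  if (nrow(m) == 0) {
    strata <- paste(
      sprintf("%s [%d-%d] %s %s", table$disease, table$age_lo,
              table$age_hi, table$sex, table$ethnicity),
      collapse = "; "
    )
    abort(sprintf("no prevalence stratum matches; available: %s", strata))
  }
  if (nrow(m) > 1) abort("ambiguous prevalence lookup: several strata match")
  m$pretest_prob
}

#' Greedy LD pruning of association records
#'
#' Keeps at most one SNP per linkage-disequilibrium cluster: records are
#' ranked by strength of evidence (number of studies, then number of
#' samples, then rsid for determinism) and accepted greedily when their r2
#' against every already-kept record is at or below `r2_max`. The result
#' never contains a pair above the threshold.
#'
#' @param records Association tibble for one disease (long format, one row
#'   per rsid and genotype; rsid-level columns n_studies, n_samples).
#' @param ld LD tibble (rsid_a, rsid_b, r2), treated as symmetric.
#' @param r2_max Maximum tolerated r2 between kept records.
#' @return The subset of `records` belonging to kept rsids.
#' @export
ld_prune <- function(records, ld, r2_max = 0.3) {
  info <- records %>%
    distinct(.data$rsid, .data$n_studies, .data$n_samples) %>%
    arrange(desc(.data$n_studies), desc(.data$n_samples), .data$rsid)
  # symmetric closure of the LD table
  ld2 <- bind_rows(
    select(ld, "rsid_a", "rsid_b", "r2"),
    tibble(rsid_a = ld$rsid_b, rsid_b = ld$rsid_a, r2 = ld$r2)
  )
  r2_of <- function(a, b) {
    hit <- ld2$r2[ld2$rsid_a == a & ld2$rsid_b %in% b]
    if (length(hit) == 0) 0 else max(hit)
  }
  kept <- character()
  for (r in info$rsid) {
    if (length(kept) == 0 || r2_of(r, kept) <= r2_max) {
      kept <- c(kept, r)
    }
  }
  filter(records, .data$rsid %in% kept)
}

#' Combine per-SNP likelihood ratios into one
#'
#' Multiplies the subject's genotype likelihood ratio over the kept (LD
#' pruned) records. A missing subject genotype, or a genotype absent from a
#' record's LR map, contributes a factor of 1 (no information) and is
#' reported. The product is accumulated in log space; the contract is the
#' plain product.
#'
#' @param genotypes Subject genotype tibble (rsid, genotype).
#' @param kept Pruned association tibble (rsid, genotype, lr, ...).
#' @return List: `lambda` (combined LR), `per_record` (tibble rsid,
#'   genotype, lr, n_studies, n_samples), `n_uninformative`.
#' @export
combined_lr <- function(genotypes, kept) {
  if (any(kept$lr <= 0 | !is.finite(kept$lr))) {
    abort("likelihood ratios must be positive and finite")
  }
  subj <- genotypes %>%
    mutate(genotype = normalise_genotype(.data$genotype)) %>%
    distinct(.data$rsid, .keep_all = TRUE)
  rec <- kept %>%
    distinct(.data$rsid, .data$n_studies, .data$n_samples)
  matched <- rec %>%
    left_join(select(subj, "rsid", "genotype"), by = "rsid") %>%
    left_join(
      kept %>% mutate(genotype = normalise_genotype(.data$genotype)) %>%
        select("rsid", "genotype", "lr"),
      by = c("rsid", "genotype")
    ) %>%
    mutate(uninformative = is.na(.data$lr),
           lr = dplyr::coalesce(.data$lr, 1))
  n_uninf <- sum(matched$uninformative)
  if (n_uninf > 0) {
    inform(sprintf(
      "%d record(s) without a usable subject genotype contribute LR = 1",
      n_uninf
    ))
  }
  list(
    lambda = exp(sum(log(matched$lr))),
    per_record = matched,
    n_uninformative = n_uninf
  )
}

#' Post-test probability from pre-test probability and a likelihood ratio
#'
#' Bayes on the odds scale: post-test odds are `lambda` times the pre-test
#' odds, so `p1 = lambda p0 / (1 - p0 + lambda p0)`. Strictly increasing in
#' both arguments; `lambda = 1` returns `p0` unchanged.
#'
#' @param p0 Pre-test probability in (0,1).
#' @param lambda Combined likelihood ratio (> 0).
#' @return Post-test probability in (0,1).
#' @examples
#' posttest_probability(0.5, 3) # 0.75
#' @export
posttest_probability <- function(p0, lambda) {
  if (any(p0 <= 0 | p0 >= 1)) abort("`p0` must lie in (0, 1)")
  if (any(lambda <= 0)) abort("`lambda` must be > 0")
  odds <- lambda * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Percentile of the subject's combined LR within a population panel
#'
#' Recomputes the combined likelihood ratio for every panel individual over
#' the same kept records (missing panel genotypes contribute a factor of 1)
#' and reports the percentage of the panel with a strictly smaller LR; ties
#' do not count.
#'
#' @param subject_lambda Subject combined LR.
#' @param panel Panel genotype tibble (individual, rsid, genotype).
#' @param kept Pruned association tibble.
#' @return List: `percentile`, `panel_lambdas` (tibble individual, lambda).
#' @export
risk_percentile <- function(subject_lambda, panel, kept) {
  if (nrow(panel) == 0) abort("empty panel")
  lambdas <- panel %>%
    group_by(.data$individual) %>%
    dplyr::group_map(function(g, key) {
      tibble(individual = key$individual,
             lambda = combined_lr(g, kept)$lambda)
    }) %>%
    bind_rows()
  list(
    percentile = 100 * sum(lambdas$lambda < subject_lambda) / nrow(lambdas),
    panel_lambdas = lambdas
  )
}

#' Cumulative post-test probability series (RiskOgram)
#'
#' Orders the kept records by decreasing number of supporting studies (ties
#' by decreasing sample count, then rsid) and reports the post-test
#' probability after incorporating each successive SNP's likelihood ratio.
#' The final entry equals the full post-test probability; with no kept
#' records the series is empty and the summary probability is `p0`.
#'
#' @param p0 Pre-test probability.
#' @param genotypes Subject genotype tibble (rsid, genotype).
#' @param kept Pruned association tibble.
#' @return A `riskogram` tibble: rsid, n_studies, n_samples, genotype, lr,
#'   cumulative_lr, cumulative_posttest; attribute `p0`.
#' @export
riskogram <- function(p0, genotypes, kept) {
  comb <- combined_lr(genotypes, kept)
  steps <- comb$per_record %>%
    arrange(desc(.data$n_studies), desc(.data$n_samples), .data$rsid) %>%
    mutate(
      cumulative_lr = cumprod(.data$lr),
      cumulative_posttest = posttest_probability(p0, .data$cumulative_lr)
    )
  attr(steps, "p0") <- p0
  class(steps) <- c("riskogram", class(steps))
  steps
}

#' Assess disease risk for one disease
#'
#' Runs the whole likelihood-ratio procedure: pre-test probability lookup,
#' per-disease LD pruning, combined LR over the subject's genotypes,
#' post-test probability, percentile against the population panel, and the
#' RiskOgram series.
#'
#' @param bundle A `risk_bundle` (or a list with the same tables).
#' @param disease Disease to assess.
#' @param age,sex,ethnicity Demographic stratum of the subject.
#' @param r2_max LD pruning threshold.
#' @return A `risk_assessment` object.
#' @export
assess_risk <- function(bundle, disease, age = 48, sex = "F",
                        ethnicity = "SA", r2_max = 0.3) {
  p0 <- pretest_probability(bundle$prevalence, disease, age, sex, ethnicity)
  records <- filter(bundle$associations, .data$disease == !!disease)
  kept <- ld_prune(records, bundle$ld, r2_max = r2_max)
  comb <- combined_lr(bundle$subject_genotypes, kept)
  p1 <- posttest_probability(p0, comb$lambda)
  pct <- risk_percentile(comb$lambda, bundle$panel, kept)
  rog <- riskogram(p0, bundle$subject_genotypes, kept)
  structure(
    list(
      disease = disease,
      pretest = p0,
      kept = kept,
      per_record = comb$per_record,
      combined_lr = comb$lambda,
      posttest = p1,
      percentile = pct$percentile,
      panel_lambdas = pct$panel_lambdas,
      riskogram = rog
    ),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("Risk assessment: %s\n", x$disease))
  cat(sprintf("  pre-test probability:  %.4f\n", x$pretest))
  cat(sprintf("  SNPs kept after LD pruning: %d\n",
              dplyr::n_distinct(x$kept$rsid)))
  cat(sprintf("  combined LR:           %.4f\n", x$combined_lr))
  cat(sprintf("  post-test probability: %.4f\n", x$posttest))
  cat(sprintf("  panel percentile:      %.1f%%\n", x$percentile))
  invisible(x)
}

#' Pharmacogenomic genotype lookup
#'
#' Returns the table rows whose rsid and (unordered) genotype both match the
#' subject; no fuzzy matching.
#'
#' @param genotypes Subject genotype tibble (rsid, genotype).
#' @param table PGx tibble (rsid, gene, genotype, drug, outcome_text).
#' @return The matching rows of `table`.
#' @export
pgx_lookup <- function(genotypes, table) {
  subj <- genotypes %>%
    mutate(genotype = normalise_genotype(.data$genotype)) %>%
    distinct(.data$rsid, .data$genotype)
  table %>%
    mutate(.gt = normalise_genotype(.data$genotype)) %>%
    semi_join(rename(subj, .gt = "genotype"), by = c("rsid", ".gt")) %>%
    select(-".gt")
}
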