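# Variant quality control: depth/quality filters, the
# heterozygous-without-reference-allele exclusion, array concordance, and
# coverage summaries against a matched-mean Poisson reference.

new_filter_report <- function(pass_set, n_input, n_fail_depth = 0L,
                              n_fail_quality = 0L, n_fail_het_no_ref = 0L,
                              thresholds = list()) {
  structure(
    list(
      n_input = n_input,
      n_pass = nrow(pass_set),
      n_fail_depth = n_fail_depth,
      n_fail_quality = n_fail_quality,
      n_fail_het_no_ref = n_fail_het_no_ref,
      pass_set = pass_set,
      thresholds = thresholds
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filter report\n")
  cat(sprintf("  input:            %d\n", x$n_input))
  cat(sprintf("  pass:             %d\n", x$n_pass))
  cat(sprintf("  fail depth:       %d\n", x$n_fail_depth))
  cat(sprintf("  fail quality:     %d\n", x$n_fail_quality))
  cat(sprintf("  fail het-no-ref:  %d\n", x$n_fail_het_no_ref))
  invisible(x)
}

#' Filter variant calls on read depth and quality
#'
#' Retains calls with `depth_min <= depth <= depth_max` (bounds inclusive)
#' and `quality >= qual_min`. The depth rule is waived on the mitochondrial
#' contig, where coverage is far higher than the nuclear genome; the quality
#' rule still applies there. A call failing several rules is attributed to
#' the first failing rule in the order depth, then quality, so the report
#' counts are additive.
#'
#' @param calls Variant-call tibble (columns contig, pos, depth, qual, ...).
#' @param depth_min,depth_max Inclusive depth bounds.
#' @param qual_min Minimum phred-scaled variant quality.
#' @param mito_contig Name of the mitochondrial contig, or `NULL`.
#' @return A `filter_report`: counts per rule plus the retained `pass_set`.
#' @examples
#' calls <- tibble::tibble(
#'   contig = "chr1", pos = 1:3, ref = "A", alt = "G",
#'   genotype = "A/G", depth = c(4L, 5L, 30L), qual = c(50, 30, 10),
#'   vtype = "snp"
#' )
#' filter_variants(calls)
#' @export
filter_variants <- function(calls, depth_min = 5, depth_max = 60,
                            qual_min = 30, mito_contig = NULL) {
  if (depth_min < 0 || qual_min < 0) abort("thresholds must be non-negative")
  if (depth_min > depth_max) abort("`depth_min` must be <= `depth_max`")
  if (!is.null(mito_contig) && !mito_contig %in% calls$contig) {
    warn(sprintf(
      "mito contig '%s' not present; depth rule applied to all contigs",
      mito_contig
    ))
  }
  depth_exempt <- if (is.null(mito_contig)) {
    rep(FALSE, nrow(calls))
  } else {
    calls$contig == mito_contig
  }
  ok_depth <- depth_exempt |
    (calls$depth >= depth_min & calls$depth <= depth_max)
  ok_qual <- calls$qual >= qual_min

  fail_depth <- !ok_depth
  fail_qual <- ok_depth & !ok_qual
  new_filter_report(
    pass_set = calls[ok_depth & ok_qual, , drop = FALSE],
    n_input = nrow(calls),
    n_fail_depth = sum(fail_depth),
    n_fail_quality = sum(fail_qual),
    thresholds = list(depth_min = depth_min, depth_max = depth_max,
                      qual_min = qual_min, mito_contig = mito_contig)
  )
}

#' Exclude heterozygous calls that share no allele with the reference
#'
#' A heterozygous genotype whose two alleles both differ from the reference
#' base at the call position is removed; homozygous calls are never touched
#' by this rule.
#'
#' @param calls Variant-call tibble.
#' @param reference Named character vector of contig sequences.
#' @return A `filter_report` with `n_fail_het_no_ref` populated.
#' @export
exclude_het_without_ref_allele <- function(calls, reference) {
  if (nrow(calls) == 0) {
    return(new_filter_report(calls, 0L))
  }
  refbase <- reference_base(reference, calls$contig, calls$pos)
  alleles <- genotype_alleles(calls$genotype)
  het <- is_heterozygous(calls$genotype)
  shares_ref <- purrr::map2_lgl(alleles, refbase, function(al, rb) {
    any(al == rb)
  })
  drop <- het & !shares_ref
  new_filter_report(
    pass_set = calls[!drop, , drop = FALSE],
    n_input = nrow(calls),
    n_fail_het_no_ref = sum(drop)
  )
}

#' Genotype concordance between sequencing and array calls
#'
#' Compares genotypes at the intersection of sites (keyed by contig and
#' position). Genotypes are compared as unordered allele pairs; sites with a
#' missing genotype on either side are excluded from the denominator. The
#' percentage is reported half-up to one decimal, the precision at which
#' such concordances are quoted.
#'
#' @param seq_genotypes,array_genotypes Tibbles with contig, pos, genotype.
#' @return List with `n_sites`, `n_concordant`, `pct`.
#' @examples
#' a <- tibble::tibble(contig = "chr1", pos = 1:4,
#'                     genotype = c("A/G", "C/C", "G/T", "A/A"))
#' b <- dplyr::mutate(a, genotype = c("G/A", "C/C", "T/T", "A/A"))
#' array_concordance(a, b)
#' @export
array_concordance <- function(seq_genotypes, array_genotypes) {
  joined <- inner_join(
    mutate(seq_genotypes, gt_seq = normalise_genotype(.data$genotype)) %>%
      select("contig", "pos", "gt_seq"),
    mutate(array_genotypes, gt_arr = normalise_genotype(.data$genotype)) %>%
      select("contig", "pos", "gt_arr"),
    by = c("contig", "pos")
  ) %>%
    filter(!is.na(.data$gt_seq), !is.na(.data$gt_arr))
  if (nrow(joined) == 0) {
    abort("no overlapping sites with genotypes on both sides")
  }
  n_conc <- sum(joined$gt_seq == joined$gt_arr)
  list(
    n_sites = nrow(joined),
    n_concordant = n_conc,
    pct = round_half_up(100 * n_conc / nrow(joined), 1)
  )
}

#' Coverage profile of a per-base depth track
#'
#' Summarises a depth track over the non-N bases of its contig: the depth
#' histogram (fraction of non-N bases at each depth), mean depth (mapped
#' bases over non-N bases), the fractions covered by at least one and at
#' least five reads, per-window GC fraction and mean depth in non-overlapping
#' windows, and the Poisson probability mass function with the same mean for
#' comparison with the observed histogram.
#'
#' @param depths Integer vector, one depth per reference base.
#' @param reference Single reference sequence (character scalar).
#' @param window Window width in bases for the GC/depth summary.
#' @return A `coverage_profile`: `histogram` (tibble depth, fraction),
#'   `mean_depth`, `frac_ge1`, `frac_ge5`, `windows` (tibble start, end, gc,
#'   mean_depth, partial), `poisson_ref` (tibble depth, pmf).
#' @export
coverage_profile <- function(depths, reference, window = 50000) {
  reference <- toupper(reference)
  n <- nchar(reference)
  if (length(depths) != n) {
    abort("`depths` must have one entry per reference base")
  }
  base <- strsplit(reference, "")[[1]]
  non_n <- base != "N"
  if (!any(non_n)) abort("reference is all N")
  d <- depths[non_n]

  tab <- table(d)
  histogram <- tibble(
    depth = as.integer(names(tab)),
    fraction = as.numeric(tab) / length(d)
  )
  mean_depth <- sum(as.numeric(d)) / length(d)

  starts <- seq(1L, n, by = window)
  wins <- purrr::map_dfr(starts, function(s) {
    e <- min(s + window - 1L, n)
    b <- base[s:e]
    dep <- depths[s:e]
    keep <- b != "N"
    tibble(
      start = s, end = e,
      gc = if (any(keep)) mean(b[keep] %in% c("G", "C")) else NA_real_,
      mean_depth = if (any(keep)) mean(dep[keep]) else NA_real_,
      n_non_n = sum(keep),
      partial = (e - s + 1L) < window
    )
  })

  dmax <- max(histogram$depth)
  structure(
    list(
      histogram = histogram,
      mean_depth = mean_depth,
      frac_ge1 = mean(d >= 1),
      frac_ge5 = mean(d >= 5),
      windows = wins,
      poisson_ref = tibble(depth = 0:dmax, pmf = dpois(0:dmax, mean_depth))
    ),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("Coverage profile\n")
  cat(sprintf("  mean depth: %.2f\n", round_half_up(x$mean_depth, 2)))
  cat(sprintf("  >=1 read:   %.2f%%\n", round_half_up(100 * x$frac_ge1, 2)))
  cat(sprintf("  >=5 reads:  %.2f%%\n", round_half_up(100 * x$frac_ge5, 2)))
  cat(sprintf("  windows:    %d\n", nrow(x$windows)))
  invisible(x)
}
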