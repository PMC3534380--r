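# Depth/quality filters, het-no-ref exclusion, concordance, coverage.

mk_calls <- function(depth, qual, genotype = "A/G", contig = "chr1") {
  tibble::tibble(
    contig = contig, pos = seq_along(depth), ref = "A", alt = "G",
    genotype = genotype, depth = depth, qual = qual, vtype = "snp"
  )
}

test_that("depth and quality bounds are inclusive, boundary cases fall as stated", {
  calls <- mk_calls(depth = c(4, 5, 60, 61, 30),
                    qual = c(50, 30, 30, 50, 29.9))
  fr <- filter_variants(calls)
  expect_equal(fr$n_pass, 2)          # depth 5/qual 30 and depth 60/qual 30
  expect_equal(fr$n_fail_depth, 2)    # depth 4 and 61
  expect_equal(fr$n_fail_quality, 1)  # qual 29.9
  expect_equal(fr$n_input,
               fr$n_pass + fr$n_fail_depth + fr$n_fail_quality +
                 fr$n_fail_het_no_ref)
  expect_s3_class(tidy(fr), "tbl_df")
  expect_equal(glance(fr)$pass_rate, 2 / 5)
})

test_that("failure attribution is first-rule-wins and counts stay additive", {
  # depth 4 AND qual 10: counted under depth only
  calls <- mk_calls(depth = c(4, 30), qual = c(10, 10))
  fr <- filter_variants(calls)
  expect_equal(fr$n_fail_depth, 1)
  expect_equal(fr$n_fail_quality, 1)
})

test_that("depth rule is waived on the mitochondrial contig, quality kept", {
  calls <- dplyr::bind_rows(
    mk_calls(depth = 4000, qual = 50, contig = "chrM"),
    mk_calls(depth = 4000, qual = 10, contig = "chrM"),
    mk_calls(depth = 4000, qual = 50, contig = "chr1")
  )
  fr <- filter_variants(calls, mito_contig = "chrM")
  expect_equal(fr$n_pass, 1)
  expect_equal(fr$n_fail_quality, 1)
  expect_equal(fr$n_fail_depth, 1)
  expect_warning(filter_variants(calls, mito_contig = "chrMT"),
                 "not present")
})

test_that("filtered pass counts match planted manifest counts exactly", {
  b <- generate_genome_bundle(seed = 51)
  calls <- generate_variant_calls(b, n_snp = 5000, n_indel = 500, seed = 52)
  man <- attr(calls, "manifest")
  fr <- filter_variants(calls)
  fr2 <- exclude_het_without_ref_allele(fr$pass_set, b$reference)
  expect_equal(fr$n_fail_depth, man$n_fail_depth)
  expect_equal(fr$n_fail_quality, man$n_fail_quality)
  expect_equal(fr2$n_fail_het_no_ref, man$n_fail_het_no_ref)
  expect_equal(fr2$n_pass, man$n_pass)
})

test_that("het-no-ref rule follows the stated genotype cases", {
  ref <- c(chr1 = "GGGGG")
  calls <- tibble::tibble(
    contig = "chr1", pos = c(1, 2, 3), ref = "G",
    alt = c("A,T", "T", "T"),
    genotype = c("A/T", "G/T", "T/T"),
    depth = 30, qual = 50, vtype = "snp"
  )
  fr <- exclude_het_without_ref_allele(calls, ref)
  # A/T excluded (no ref allele); G/T retained; homozygous T/T retained
  expect_equal(fr$n_fail_het_no_ref, 1)
  expect_equal(fr$pass_set$genotype, c("G/T", "T/T"))

  bad <- dplyr::mutate(calls[1, ], pos = 99)
  expect_error(exclude_het_without_ref_allele(bad, ref), "beyond")
})

test_that("filter rules are conjunctive: order does not change the pass set", {
  b <- generate_genome_bundle(seed = 53)
  calls <- generate_variant_calls(b, n_snp = 1000, n_indel = 100, seed = 54)
  a <- exclude_het_without_ref_allele(
    filter_variants(calls)$pass_set, b$reference)$pass_set
  b2 <- filter_variants(
    exclude_het_without_ref_allele(calls, b$reference)$pass_set)$pass_set
  expect_equal(dplyr::arrange(a, contig, pos),
               dplyr::arrange(b2, contig, pos))
})

test_that("concordance reproduces the published identity and basic cases", {
  # 989,747 concordant of 1,003,031 sites is 98.7% at one decimal
  expect_equal(round_half_up(100 * 989747 / 1003031, 1), 98.7)

  a <- tibble::tibble(contig = "chr1", pos = 1:4,
                      genotype = c("A/G", "C/C", "T/G", "A/A"))
  expect_equal(array_concordance(a, a)$pct, 100.0)
  # unordered comparison: G/A equals A/G
  b <- dplyr::mutate(a, genotype = c("G/A", "C/C", "G/T", "A/A"))
  expect_equal(array_concordance(a, b)$pct, 100.0)
  # symmetry
  c2 <- dplyr::mutate(a, genotype = c("G/G", "C/C", "G/T", "A/A"))
  expect_equal(array_concordance(a, c2)$n_concordant,
               array_concordance(c2, a)$n_concordant)
  # missing genotypes drop out of the denominator
  d <- dplyr::mutate(a, genotype = c("./.", "C/C", "G/T", "A/A"))
  expect_equal(array_concordance(a, d)$n_sites, 3)
  # empty intersection errors rather than reporting 0%
  e <- dplyr::mutate(a, contig = "chr2")
  expect_error(array_concordance(a, e), "no overlapping")
})

test_that("coverage profile handles constant depth and reports exact fractions", {
  ref <- paste(rep("ACGT", 25), collapse = "")
  prof <- coverage_profile(rep(10L, 100), ref, window = 40)
  expect_equal(prof$histogram$depth, 10)
  expect_equal(prof$histogram$fraction, 1)
  expect_equal(prof$mean_depth, 10)
  expect_equal(prof$frac_ge1, 1)
  expect_equal(prof$frac_ge5, 1)
  # three windows: 40 + 40 + 20 (final partial window kept and flagged)
  expect_equal(nrow(prof$windows), 3)
  expect_equal(prof$windows$partial, c(FALSE, FALSE, TRUE))
  expect_error(coverage_profile(rep(1L, 3), "NNN"), "all N")
  expect_error(coverage_profile(rep(1L, 3), "ACGT"), "one entry per")
})

test_that("N bases are excluded from denominators but windows conserve GC", {
  ref <- "ACGTNNGGCC"
  depths <- c(1L, 2L, 3L, 4L, 9L, 9L, 5L, 6L, 7L, 8L)
  prof <- coverage_profile(depths, ref, window = 5)
  expect_equal(prof$mean_depth, mean(c(1, 2, 3, 4, 5, 6, 7, 8)))
  # GC conservation: sum over windows of gc * n_non_n equals total G+C
  total_gc <- sum(prof$windows$gc * prof$windows$n_non_n)
  expect_equal(total_gc, 6) # G,C in ACGT + GGCC
})

test_that("histogram matches the Poisson reference for Poisson-drawn depths", {
  n <- 100000
  d <- withr::with_seed(77, stats::rpois(n, 30))
  ref <- paste(withr::with_seed(78,
    sample(c("A", "C", "G", "T"), n, replace = TRUE)), collapse = "")
  prof <- coverage_profile(d, ref, window = n)
  joined <- tidy(prof)
  tv <- 0.5 * sum(abs(joined$fraction - joined$poisson_pmf))
  expect_lt(tv, 0.02)
  expect_equal(sum(prof$histogram$fraction), 1, tolerance = 1e-9)
  expect_lte(prof$frac_ge5, prof$frac_ge1)
})
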