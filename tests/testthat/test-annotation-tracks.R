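# Repeat/regulatory overlap, TSS metaprofile, gene-set enrichment.

test_that("repeat overlap counts match a nested-loop scan", {
  b <- generate_genome_bundle(seed = 71)
  calls <- generate_variant_calls(b, n_snp = 400, n_indel = 60, seed = 72)
  res <- repeat_overlap(calls, b$repeats)
  pairs <- oracle_overlap_pairs(pgint:::variant_span(calls), b$repeats)
  pairs$class <- b$repeats$class[pairs$f]
  expect_equal(res$n_in_repeat, length(unique(pairs$v)))
  want <- dplyr::count(dplyr::distinct(pairs, v, class), class, name = "n")
  got <- dplyr::arrange(res$class_counts[, c("class", "n")], class)
  expect_equal(as.data.frame(got), as.data.frame(dplyr::arrange(want, class)))
  # empty repeat track
  empty <- repeat_overlap(calls, b$repeats[0, ])
  expect_equal(empty$n_in_repeat, 0)
})

test_that("a variant in two repeat classes counts once per class, once in the denominator", {
  calls <- tibble::tibble(contig = "c", pos = 100L, ref = "A", alt = "G",
                          genotype = "A/G", depth = 30, qual = 50,
                          vtype = "snp")
  reps <- tibble::tibble(
    contig = "c", start = c(50L, 90L), end = c(150L, 120L),
    name = c("r1", "r2"), class = c("LINE", "Simple_repeat"),
    family = c("L1", "(TA)n")
  )
  res <- repeat_overlap(calls, reps)
  expect_equal(res$n_in_repeat, 1)
  expect_equal(sort(res$class_counts$class), c("LINE", "Simple_repeat"))
  expect_equal(res$class_counts$n, c(1L, 1L))
  expect_equal(res$per_variant_classes, "LINE,Simple_repeat")
})

test_that("TSS profile mirrors minus-strand transcripts and handles no variants", {
  tx <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", contig = "c", strand = "-",
    feature = "exon", start = 8000L, end = 10000L
  )
  # TSS is the exon end (10,000) on the minus strand; a variant at 10,100
  # is upstream, in the bin covering -100
  v <- tibble::tibble(contig = "c", pos = 10100L, ref = "A", alt = "G",
                      genotype = "A/G", depth = 30, qual = 50, vtype = "snp")
  prof <- tss_profile(v, tx, half_window = 2000, bin = 50)
  hit <- prof[prof$n > 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$bin_start, -100)
  expect_equal(hit$mean_per_transcript, 1)

  zero <- tss_profile(v[0, ], tx)
  expect_true(all(zero$n == 0))
  expect_error(tss_profile(v, tx, half_window = 2000, bin = 33),
               "multiple")
})

test_that("a planted central enrichment is recovered from the profile", {
  tx <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", contig = "c", strand = "+",
    feature = "exon", start = 50000L, end = 52000L
  )
  tss <- 50000L
  n <- 5000
  hw <- 2000
  rel <- withr::with_seed(73, {
    # density 3x in [-50, 50) relative to the flat background
    central <- runif(n) < (3 * 100) / (3 * 100 + (2 * hw - 100))
    ifelse(central,
           floor(runif(n, -50, 50)),
           sample(c(seq(-hw, -51), seq(50, hw - 1)), n, replace = TRUE))
  })
  v <- tibble::tibble(contig = "c", pos = as.integer(tss + rel), ref = "A",
                      alt = "G", genotype = "A/G", depth = 30, qual = 50,
                      vtype = "snp")
  prof <- tss_profile(v, tx, half_window = hw, bin = 50)
  central_bins <- prof$bin_start %in% c(-50, 0)
  ratio <- mean(prof$n[central_bins]) / mean(prof$n[!central_bins])
  expect_lt(abs(ratio - 3), 0.5)
})

test_that("TFBS hits require the 5-kb upstream window, enhancers do not", {
  tx <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", contig = "c", strand = "+",
    feature = "exon", start = 20000L, end = 21000L
  )
  feats <- tibble::tibble(
    contig = "c",
    start = c(13990L, 16000L, 100L),
    end = c(14010L, 16020L, 400L),
    kind = c("tfbs", "tfbs", "enhancer"),
    label = c("far", "near", "e1")
  )
  v <- tibble::tibble(
    contig = "c", pos = c(14000L, 16010L, 200L), ref = "A", alt = "G",
    genotype = "A/G", depth = 30, qual = 50, vtype = "snp"
  )
  res <- regulatory_overlap(v, feats, tx)
  counts <- res$counts
  # the TFBS 6 kb upstream does not count; the one at -5k..-4k does
  expect_equal(counts$n[counts$kind == "tfbs" & counts$vtype == "snp"], 1L)
  expect_equal(counts$n[counts$kind == "enhancer" & counts$vtype == "snp"],
               1L)
  none <- regulatory_overlap(v[0, ], feats, tx)
  expect_true(all(none$counts$n == 0))
})

test_that("regulatory counts equal a brute-force triple-overlap scan", {
  b <- generate_genome_bundle(seed = 75)
  calls <- generate_variant_calls(b, n_snp = 400, n_indel = 50, seed = 76)
  res <- regulatory_overlap(calls, b$regulatory, b$transcripts)
  span <- pgint:::variant_span(calls)
  win <- upstream_windows(b$transcripts)
  expected <- list(tfbs = integer(), enhancer = integer())
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(b$regulatory))) {
      f <- b$regulatory[j, ]
      if (span$contig[i] != f$contig ||
          span$start[i] > f$end || f$start > span$end[i]) next
      if (f$kind == "tfbs") {
        inwin <- FALSE
        for (k in seq_len(nrow(win))) {
          if (span$contig[i] == win$contig[k] &&
              span$start[i] <= win$end[k] &&
              win$start[k] <= span$end[i]) {
            inwin <- TRUE
          }
        }
        if (inwin) expected$tfbs <- union(expected$tfbs, i)
      } else {
        expected$enhancer <- union(expected$enhancer, i)
      }
    }
  }
  for (kind in c("tfbs", "enhancer")) {
    for (vt in c("snp", "indel")) {
      got <- res$counts$n[res$counts$kind == kind & res$counts$vtype == vt]
      want <- sum(calls$vtype[expected[[kind]]] == vt)
      expect_equal(got, want, info = paste(kind, vt))
    }
  }
})

test_that("hypergeometric enrichment matches direct tail summation", {
  universe <- sprintf("g%03d", 1:100)
  hits <- universe[1:20]
  sets <- list(
    whole = universe,            # p = 1 exactly
    top = universe[c(1:5, 90:94)],  # k = 5, K = 10
    none = universe[95:100]      # k = 0: p = 1 under the >=-tail convention
  )
  res <- geneset_enrichment(hits, universe, sets)
  expect_equal(res$p[res$set == "whole"], 1)
  expect_equal(res$p[res$set == "none"], 1)
  expect_equal(res$p[res$set == "top"],
               oracle_hyper_tail(5, 10, 100, 20), tolerance = 1e-12)
  # BH q-values are monotone in the p ranking
  ordered <- res[order(res$p), ]
  expect_true(all(diff(ordered$q) >= -1e-12))
  expect_error(geneset_enrichment(hits, character(), sets), "empty")
  expect_error(geneset_enrichment(c(hits, "zzz"), universe, sets),
               "subset")
})
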