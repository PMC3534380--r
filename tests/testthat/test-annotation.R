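# Region classification and codon-level consequence calling.

test_that("region labels match an exhaustive per-transcript scan", {
  b <- generate_genome_bundle(seed = 61)
  calls <- generate_variant_calls(b, n_snp = 450, n_indel = 50, seed = 62)
  res <- classify_region(calls, b$transcripts)
  span <- pgint:::variant_span(calls)
  expected <- vapply(seq_len(nrow(calls)), function(i) {
    oracle_region(span$start[i], span$end[i], span$contig[i],
                  b$transcripts)
  }, character(1))
  expect_equal(res$region, expected)
})

test_that("region labels are exhaustive and mutually exclusive", {
  b <- generate_genome_bundle(seed = 63)
  calls <- generate_variant_calls(b, n_snp = 500, n_indel = 0, seed = 64)
  res <- classify_region(calls, b$transcripts)
  expect_true(all(res$region %in% c("coding_exon", "utr5", "utr3",
                                    "noncoding_exon", "intron",
                                    "intergenic")))
  expect_equal(length(res$region), nrow(calls))
  # no transcripts at all: everything intergenic
  none <- classify_region(calls, b$transcripts[0, ])
  expect_true(all(none$region == "intergenic"))
})

test_that("single-codon substitutions translate as the genetic code dictates", {
  fx <- fixture_single_exon_tx("ATGGCTCGATAA") # Met-Ala-Arg-stop
  # GCT -> GCC (third base T>C): synonymous Ala
  v1 <- tibble::tibble(contig = "ctg", pos = fx$cds_start + 5L, ref = "T",
                       alt = "C", vtype = "snp")
  e1 <- coding_effect_snp(v1, fx$tx, fx$reference)
  expect_equal(e1$effect, "synonymous")
  expect_equal(e1$codon, 2L)
  # CGA -> TGA (first base C>T): nonsense
  v2 <- tibble::tibble(contig = "ctg", pos = fx$cds_start + 6L, ref = "C",
                       alt = "T", vtype = "snp")
  e2 <- coding_effect_snp(v2, fx$tx, fx$reference)
  expect_equal(e2$effect, "nonsense")
  expect_equal(e2$codon, 3L)
  # outside the CDS: directed to classify_region
  v3 <- tibble::tibble(contig = "ctg", pos = 5L, ref = "A", alt = "G",
                       vtype = "snp")
  expect_error(coding_effect_snp(v3, fx$tx, fx$reference), "classify_region")
})

test_that("all nine single-base changes of a codon match table translation", {
  for (strand in c("+", "-")) {
    fx <- fixture_single_exon_tx("ATGAAATAA", strand = strand) # Met-Lys-stop
    # codon 2 is AAA; enumerate all single-base substitutions
    for (within in 0:2) {
      genomic_off <- if (strand == "+") 3L + within else 5L - within
      pos <- fx$cds_start + genomic_off
      rb <- substr(fx$reference[["ctg"]], pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), rb)) {
        v <- tibble::tibble(contig = "ctg", pos = pos, ref = rb, alt = alt,
                            vtype = "snp")
        got <- coding_effect_snp(v, fx$tx, fx$reference)
        alt_t <- if (strand == "-") chartr("ACGT", "TGCA", alt) else alt
        codon <- "AAA"
        substr(codon, within + 1, within + 1) <- alt_t
        aa <- oracle_translate_codon(codon)
        want <- if (aa == "*") "nonsense" else if (aa == "K") {
          "synonymous"
        } else {
          "missense"
        }
        expect_equal(got$effect, want,
                     info = sprintf("%s strand codon %s", strand, codon))
      }
    }
  }
})

test_that("coding SNP effects are invariant under a whole-genome strand flip", {
  b <- generate_genome_bundle(seed = 65)
  calls <- generate_variant_calls(b, n_snp = 400, n_indel = 0,
                                  exonic_fraction = 0.5, seed = 66)
  ann <- classify_region(calls, b$transcripts)
  coding <- ann[ann$region == "coding_exon", ]
  tx_split <- split(b$transcripts, b$transcripts$transcript_id)

  # reverse-complement the genome: position p maps to L - p + 1
  lens <- vapply(b$reference, nchar, integer(1))
  ref_rc <- setNames(revcomp(b$reference), names(b$reference))
  flip_tx <- function(tx) {
    L <- lens[[tx$contig[1]]]
    dplyr::mutate(tx,
      start2 = L - end + 1L, end2 = L - start + 1L,
      strand = ifelse(strand == "+", "-", "+")
    ) |>
      dplyr::mutate(start = start2, end = end2) |>
      dplyr::select(-start2, -end2)
  }
  for (i in seq_len(nrow(coding))) {
    v <- coding[i, ]
    tx <- tx_split[[v$region_transcript_id]]
    eff <- coding_effect_snp(v, tx, b$reference)
    L <- lens[[v$contig]]
    v2 <- dplyr::mutate(v, pos = L - pos + 1L,
                        ref = chartr("ACGT", "TGCA", ref),
                        alt = chartr("ACGT", "TGCA", alt))
    eff2 <- coding_effect_snp(v2, flip_tx(tx), ref_rc)
    expect_equal(eff2$effect, eff$effect)
    expect_equal(eff2$codon, eff$codon)
  }
})

test_that("indel frame arithmetic and premature stops follow translation", {
  # CDS: ATG AAA CCC GGG TTT TAA
  fx <- fixture_single_exon_tx("ATGAAACCCGGGTTTTAA")
  # 3-bp deletion fully in CDS: in-frame
  p <- fx$cds_start + 2L
  d3 <- tibble::tibble(
    contig = "ctg", pos = p,
    ref = substr(fx$reference[["ctg"]], p, p + 3L),
    alt = substr(fx$reference[["ctg"]], p, p), vtype = "indel"
  )
  e <- coding_effect_indel(d3, fx$tx, fx$reference)
  expect_equal(e$effect, "inframe")
  expect_equal(e$net_cds_change, -3)
  # 2-bp deletion: frameshift
  d2 <- dplyr::mutate(d3, ref = substr(fx$reference[["ctg"]], p, p + 2L))
  e2 <- coding_effect_indel(d2, fx$tx, fx$reference)
  expect_equal(e2$effect, "frameshift")

  # frameshift premature stop equals brute-force translation of the
  # mutated CDS: insert one base, translate, find the first stop
  orf <- "ATGAAACCCGGGTTTTAA"
  ins_after <- 4L # genomic anchor offset within the CDS
  anchor <- fx$cds_start + ins_after - 1L
  rb <- substr(fx$reference[["ctg"]], anchor, anchor)
  vi <- tibble::tibble(contig = "ctg", pos = anchor, ref = rb,
                       alt = paste0(rb, "T"), vtype = "indel")
  ei <- coding_effect_indel(vi, fx$tx, fx$reference)
  expect_equal(ei$effect, "frameshift")
  mutated <- paste0(substr(orf, 1, ins_after), "T",
                    substr(orf, ins_after + 1, nchar(orf)))
  aa <- vapply(seq(1, nchar(mutated) - 2, by = 3), function(s) {
    oracle_translate_codon(substr(mutated, s, s + 2))
  }, character(1))
  expect_equal(ei$stop_codon_at, which(aa == "*")[1])
})

test_that("a long frameshifted ORF reports its premature stop index", {
  # built so that a 1-bp insertion in codon 147 shifts the frame and the
  # first downstream stop lands at codon 179
  body <- withr::with_seed(123, {
    code <- Biostrings::GENETIC_CODE
    nonstop <- names(code)[code != "*"]
    paste(sample(nonstop, 250, replace = TRUE), collapse = "")
  })
  orf <- paste0("ATG", body, "TAA")
  fx <- fixture_single_exon_tx(orf)
  anchor <- fx$cds_start + (146L * 3L) # first base of codon 147
  rb <- substr(fx$reference[["ctg"]], anchor, anchor)
  vi <- tibble::tibble(contig = "ctg", pos = anchor, ref = rb,
                       alt = paste0(rb, "A"), vtype = "indel")
  ei <- coding_effect_indel(vi, fx$tx, fx$reference)
  expect_equal(ei$effect, "frameshift")
  # oracle: splice the base into the ORF string and translate directly
  off <- anchor - fx$cds_start + 1L
  mutated <- paste0(substr(orf, 1, off), "A",
                    substr(orf, off + 1, nchar(orf)))
  aa <- vapply(seq(1, nchar(mutated) - 2, by = 3), function(s) {
    oracle_translate_codon(substr(mutated, s, s + 2))
  }, character(1))
  expect_equal(ei$stop_codon_at, which(aa == "*")[1])
  expect_equal(ei$premature_stop_at, which(aa == "*")[1])
  expect_gt(ei$premature_stop_at, 147)
})

test_that("coding-effect categories partition coding-exon SNPs", {
  b <- generate_genome_bundle(seed = 67)
  calls <- generate_variant_calls(b, n_snp = 600, n_indel = 60,
                                  exonic_fraction = 0.4, seed = 68)
  ann <- annotate_variants(calls, b)
  coding_snps <- ann[ann$region == "coding_exon" & ann$vtype == "snp", ]
  expect_true(all(coding_snps$coding_effect %in%
                    c("synonymous", "missense", "nonsense")))
  expect_equal(
    sum(coding_snps$coding_effect == "synonymous") +
      sum(coding_snps$coding_effect == "missense") +
      sum(coding_snps$coding_effect == "nonsense"),
    nrow(coding_snps)
  )
  # effects only ever occur on coding-exon variants
  expect_true(all(ann$coding_effect[ann$region != "coding_exon"] == "none"))
})
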