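# Synthetic diploid-genome bundle: reference sequence, gene models, repeat
# and regulatory tracks, and a circular mitochondrial reference, all with
# planted ground truth recorded in a manifest. Every downstream stage of the
# pipeline is exercised against these bundles, so the generator is
# first-class, tested code rather than a fixture.

REPEAT_CLASSES <- tibble::tribble(
  ~class,          ~family,       ~weight,
  "LINE",          "L1",          0.41,
  "SINE",          "Alu",         0.30,
  "Simple_repeat", "(TA)n",       0.10,
  "LTR",           "ERV1",        0.12,
  "DNA",           "hAT-Charlie", 0.07
)

TFBS_LABELS <- c("FOXJ2", "MEF2", "TBXT", "VSX2", "PPARG", "NFKB1", "SP1")

#' Generate a synthetic genome bundle with planted annotation tracks
#'
#' Builds a small random reference genome carrying gene models (multi-exon
#' transcripts with UTRs and an in-frame open reading frame written into the
#' sequence), a repeat track with class/family labels in proportions echoing
#' a human genome (LINE/L1-heavy, then SINE/Alu), transcription-factor
#' binding sites placed relative to gene 5-kb upstream windows, enhancers,
#' and a circular mitochondrial reference partitioned into control,
#' non-coding, RNA-gene and protein-coding regions. Ground truth (counts,
#' placements, the seed) is recorded in `manifest` so tests can check every
#' downstream count against the construction.
#'
#' @param contig_lengths Named integer vector of contig lengths (each >= 10 kb).
#' @param n_genes Number of genes (one transcript per gene).
#' @param n_repeats Number of repeat features (mutually non-overlapping).
#' @param n_tfbs Number of TFBS features.
#' @param n_enhancers Number of enhancer features.
#' @param tfbs_in_window_frac Fraction of TFBS placed inside some gene's 5-kb
#'   upstream window; the rest are planted 5-6 kb upstream, just outside it.
#' @param mt_length Length of the circular mitochondrial reference (>= 2000).
#' @param seed Integer seed; the whole bundle is a deterministic function of it.
#' @return A `genome_bundle` list: `reference` (named character vector),
#'   `transcripts` (feature tibble: transcript_id, gene_id, contig, strand,
#'   feature, start, end), `repeats`, `regulatory`, `mt_reference`,
#'   `mt_regions`, `manifest`.
#' @examples
#' b <- generate_genome_bundle(seed = 1)
#' b$manifest$n_genes
#' @export
generate_genome_bundle <- function(contig_lengths = c(chr1 = 100000L),
                                   n_genes = 5,
                                   n_repeats = 25,
                                   n_tfbs = 12,
                                   n_enhancers = 6,
                                   tfbs_in_window_frac = 0.75,
                                   mt_length = 6000,
                                   seed) {
  if (missing(seed)) abort("`seed` is required")
  if (any(contig_lengths < 10000)) abort("contig lengths must be >= 10 kb")
  if (is.null(names(contig_lengths)) || any(names(contig_lengths) == "")) {
    abort("`contig_lengths` must be named")
  }
  assert_fraction(tfbs_in_window_frac, "tfbs_in_window_frac")
  if (mt_length < 2000) abort("`mt_length` must be >= 2000")

  with_seed(seed, {
    reference <- vapply(contig_lengths, random_dna, character(1))

    # genes spread across contigs proportionally to length, laid out in
    # equal slots with a 6-kb head margin so upstream windows fit
    gene_alloc <- table(factor(
      sample(names(contig_lengths), n_genes, replace = TRUE,
             prob = contig_lengths / sum(contig_lengths)),
      levels = names(contig_lengths)
    ))
    transcripts <- list()
    gi <- 0L
    for (ctg in names(contig_lengths)) {
      ng <- gene_alloc[[ctg]]
      if (ng == 0) next
      usable_lo <- 6001L
      usable_hi <- contig_lengths[[ctg]] - 500L
      slot_w <- (usable_hi - usable_lo + 1L) %/% ng
      for (j in seq_len(ng)) {
        gi <- gi + 1L
        slot_lo <- usable_lo + (j - 1L) * slot_w
        tx <- build_transcript(
          id = sprintf("tx%03d", gi), gene_id = sprintf("gene%03d", gi),
          contig = ctg, slot_lo = slot_lo, slot_hi = slot_lo + slot_w - 1L,
          strand = sample(c("+", "-"), 1)
        )
        reference[[ctg]] <- write_spliced(
          reference[[ctg]],
          tx[tx$feature == "CDS", c("start", "end")],
          tx$strand[1],
          random_orf(sum(tx$end[tx$feature == "CDS"] -
                           tx$start[tx$feature == "CDS"] + 1L) %/% 3L)
        )
        transcripts[[gi]] <- tx
      }
    }
    transcripts <- bind_rows(transcripts)

    gene_spans <- transcripts %>%
      group_by(.data$gene_id, .data$contig) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                strand = first(.data$strand), .groups = "drop")

    repeats <- place_repeats(contig_lengths, n_repeats)
    regulatory <- place_regulatory(
      contig_lengths, gene_spans, transcripts,
      n_tfbs, n_enhancers, tfbs_in_window_frac
    )

    mt <- build_mt_reference(mt_length)

    n_tfbs_in_window <- sum(regulatory$kind == "tfbs" & regulatory$in_window)
    manifest <- list(
      seed = seed,
      contig_lengths = as.list(contig_lengths),
      n_genes = n_genes,
      n_transcripts = length(unique(transcripts$transcript_id)),
      n_repeats = nrow(repeats),
      repeat_class_counts = as.list(table(repeats$class)),
      repeats_non_overlapping = TRUE,
      n_tfbs = sum(regulatory$kind == "tfbs"),
      n_tfbs_in_upstream_window = n_tfbs_in_window,
      n_enhancers = sum(regulatory$kind == "enhancer"),
      mt_length = mt_length,
      mt_region_counts = as.list(table(mt$regions$category))
    )

    structure(
      list(
        reference = reference,
        transcripts = transcripts,
        repeats = repeats,
        regulatory = select(regulatory, -"in_window"),
        mt_reference = mt$sequence,
        mt_regions = mt$regions,
        manifest = manifest
      ),
      class = "genome_bundle"
    )
  })
}

# One multi-exon transcript inside [slot_lo, slot_hi]; returns a feature
# tibble with exon / CDS / five_prime_UTR / three_prime_UTR rows. The CDS
# length is a multiple of 3 by construction.
build_transcript <- function(id, gene_id, contig, slot_lo, slot_hi, strand) {
  n_exons <- sample(2:4, 1)
  exon_len <- sample(200:400, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1) sample(200:800, n_exons - 1, replace = TRUE) else integer()
  span <- sum(exon_len) + sum(intron_len)
  max_start <- slot_hi - span + 1L
  if (max_start <= slot_lo) max_start <- slot_lo + 1L
  g0 <- sample(slot_lo:max_start, 1)

  starts <- g0 + cumsum(c(0L, head(exon_len, -1) + intron_len))
  ends <- starts + exon_len - 1L
  L <- sum(exon_len)

  u5 <- sample(30:90, 1)
  u3 <- sample(30:90, 1)
  cds_len <- L - u5 - u3
  u3 <- u3 + cds_len %% 3L
  cds_len <- L - u5 - u3
  stopifnot(cds_len %% 3L == 0L, cds_len >= 60L)

  # spliced coordinates run in transcript orientation
  spliced_cds <- c(u5 + 1L, L - u3)
  spliced_u5 <- if (u5 > 0) c(1L, u5) else NULL
  spliced_u3 <- if (u3 > 0) c(L - u3 + 1L, L) else NULL

  map_spliced <- function(rng) {
    if (is.null(rng)) return(NULL)
    # exon order in transcript orientation
    ord <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
    offs <- cumsum(c(0L, exon_len[ord][-n_exons]))
    out <- list()
    for (t in seq_len(n_exons)) {
      e <- ord[t]
      lo <- max(rng[1], offs[t] + 1L)
      hi <- min(rng[2], offs[t] + exon_len[e])
      if (lo > hi) next
      if (strand == "+") {
        gs <- starts[e] + (lo - offs[t] - 1L)
        ge <- starts[e] + (hi - offs[t] - 1L)
      } else {
        gs <- ends[e] - (hi - offs[t] - 1L)
        ge <- ends[e] - (lo - offs[t] - 1L)
      }
      out[[length(out) + 1L]] <- c(gs, ge)
    }
    do.call(rbind, out)
  }

  rows <- list(tibble(feature = "exon", start = starts, end = ends))
  for (ft in list(c("CDS", "cds"), c("five_prime_UTR", "u5"),
                  c("three_prime_UTR", "u3"))) {
    rng <- switch(ft[2], cds = spliced_cds, u5 = spliced_u5, u3 = spliced_u3)
    m <- map_spliced(rng)
    if (!is.null(m)) {
      rows[[length(rows) + 1L]] <-
        tibble(feature = ft[1], start = m[, 1], end = m[, 2])
    }
  }
  bind_rows(rows) %>%
    mutate(transcript_id = id, gene_id = gene_id, contig = contig,
           strand = strand) %>%
    select("transcript_id", "gene_id", "contig", "strand",
           "feature", "start", "end") %>%
    arrange(.data$start, .data$feature)
}

place_repeats <- function(contig_lengths, n_repeats) {
  if (n_repeats == 0) {
    return(tibble(
      contig = character(), start = integer(), end = integer(),
      name = character(), class = character(), family = character()
    ))
  }
  rows <- list()
  taken <- lapply(contig_lengths, function(x) NULL)
  i <- 0L
  guard <- 0L
  while (i < n_repeats && guard < n_repeats * 200L) {
    guard <- guard + 1L
    ctg <- sample(names(contig_lengths), 1,
                  prob = contig_lengths / sum(contig_lengths))
    len <- sample(150:1500, 1)
    start <- sample(seq_len(contig_lengths[[ctg]] - len), 1)
    end <- start + len - 1L
    prev <- taken[[ctg]]
    if (!is.null(prev) &&
        any(spans_overlap(start, end, prev[, 1], prev[, 2]))) next
    taken[[ctg]] <- rbind(prev, c(start, end))
    cls <- REPEAT_CLASSES[
      sample(nrow(REPEAT_CLASSES), 1, prob = REPEAT_CLASSES$weight), ]
    i <- i + 1L
    rows[[i]] <- tibble(
      contig = ctg, start = start, end = end,
      name = sprintf("rep%03d", i), class = cls$class, family = cls$family
    )
  }
  bind_rows(rows) %>% arrange(.data$contig, .data$start)
}

place_regulatory <- function(contig_lengths, gene_spans, transcripts,
                             n_tfbs, n_enhancers, tfbs_in_window_frac) {
  tss_tbl <- transcript_tss(transcripts)
  rows <- list()
  n_in <- round(n_tfbs * tfbs_in_window_frac)
  for (i in seq_len(n_tfbs)) {
    g <- tss_tbl[sample(nrow(tss_tbl), 1), ]
    len <- sample(10:30, 1)
    inside <- i <= n_in
    # offset of the window start from the TSS, strand-aware
    off <- if (inside) sample(100:(5000 - len), 1) else sample(5001:5800, 1)
    if (g$strand == "+") {
      end <- g$tss - off
      start <- end - len + 1L
    } else {
      start <- g$tss + off
      end <- start + len - 1L
    }
    start <- max(1L, start)
    rows[[length(rows) + 1L]] <- tibble(
      contig = g$contig, start = start, end = end, kind = "tfbs",
      label = sample(TFBS_LABELS, 1), in_window = inside
    )
  }
  for (i in seq_len(n_enhancers)) {
    ctg <- sample(names(contig_lengths), 1)
    len <- sample(200:800, 1)
    start <- sample(seq_len(contig_lengths[[ctg]] - len), 1)
    rows[[length(rows) + 1L]] <- tibble(
      contig = ctg, start = start, end = start + len - 1L,
      kind = "enhancer", label = sprintf("VISTA_hs%03d", i), in_window = NA
    )
  }
  out <- bind_rows(rows) %>% arrange(.data$contig, .data$start)
  # record the realised truth: a TFBS counts as in-window if it overlaps ANY
  # gene's upstream window, not just the one it was planted against
  win <- upstream_windows(transcripts)
  out$in_window <- ifelse(
    out$kind == "tfbs",
    purrr::map2_lgl(seq_len(nrow(out)), out$contig, function(i, ctg) {
      w <- win[win$contig == ctg, ]
      any(spans_overlap(out$start[i], out$end[i], w$start, w$end))
    }),
    NA
  )
  out
}

#' Strand-aware transcription start sites
#'
#' The TSS is the 5-prime end of the transcript: the smallest exon start on
#' the plus strand, the largest exon end on the minus strand.
#'
#' @param transcripts Feature tibble as in [generate_genome_bundle()].
#' @return Tibble with transcript_id, gene_id, contig, strand, tss.
#' @export
transcript_tss <- function(transcripts) {
  transcripts %>%
    filter(.data$feature == "exon") %>%
    group_by(.data$transcript_id, .data$gene_id, .data$contig, .data$strand) %>%
    summarise(
      tss = if (first(.data$strand) == "+") min(.data$start) else max(.data$end),
      .groups = "drop"
    )
}

# Circular mt reference partitioned into control (wrapping the origin),
# RNA-gene, non-coding and protein-coding regions; protein regions carry a
# planted ORF (frame 0 from the region start, plus strand).
build_mt_reference <- function(mt_length) {
  seq <- random_dna(mt_length)
  control_tail <- 200L   # bases before the origin
  control_head <- 250L   # bases after it
  linear_lo <- control_head + 1L
  linear_hi <- mt_length - control_tail
  linear <- linear_hi - linear_lo + 1L

  rna1 <- round(linear * 0.2)
  nc <- 100L
  prot1 <- 3L * (round(linear * 0.25) %/% 3L)
  rna2 <- round(linear * 0.05)
  prot2 <- linear - rna1 - nc - prot1 - rna2
  nc <- nc + prot2 %% 3L
  prot2 <- prot2 - prot2 %% 3L

  b <- linear_lo
  regions <- tibble(
    start = c(mt_length - control_tail + 1L,
              b, b + rna1, b + rna1 + nc, b + rna1 + nc + prot1,
              b + rna1 + nc + prot1 + rna2),
    end = c(control_head,
            b + rna1 - 1L, b + rna1 + nc - 1L, b + rna1 + nc + prot1 - 1L,
            b + rna1 + nc + prot1 + rna2 - 1L, linear_hi),
    category = c("control", "rna", "noncoding", "protein_coding",
                 "rna", "protein_coding"),
    strand = "+",
    frame = 0L
  )

  mito_code <- Biostrings::getGeneticCode("SGC1")
  for (i in which(regions$category == "protein_coding")) {
    iv <- tibble(start = regions$start[i], end = regions$end[i])
    orf <- random_orf((regions$end[i] - regions$start[i] + 1L) %/% 3L,
                      code = mito_code)
    seq <- write_spliced(seq, iv, "+", orf)
  }
  list(sequence = seq, regions = regions)
}
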