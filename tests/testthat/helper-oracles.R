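# Independent brute-force oracles. These deliberately avoid the package's
# interval/index machinery: plain loops and direct table lookups only.

library(dplyr)

# Region label for one position/span by exhaustive scan over every
# transcript's intervals, replicating the severity hierarchy by hand.
oracle_region <- function(vstart, vend, vcontig, transcripts) {
  sev <- c(intergenic = 1, intron = 2, noncoding_exon = 3, utr3 = 4,
           utr5 = 5, coding_exon = 6)
  best <- "intergenic"
  for (tid in unique(transcripts$transcript_id)) {
    tx <- transcripts[transcripts$transcript_id == tid, ]
    if (tx$contig[1] != vcontig) next
    exons <- tx[tx$feature == "exon", ]
    cds <- tx[tx$feature == "CDS", ]
    span_lo <- min(tx$start); span_hi <- max(tx$end)
    hit <- function(a, b) vstart <= b && a <= vend
    labels <- character()
    for (i in seq_len(nrow(cds))) {
      if (hit(cds$start[i], cds$end[i])) labels <- c(labels, "coding_exon")
    }
    if (nrow(cds) > 0) {
      lo <- min(cds$start); hi <- max(cds$end)
      left_lab <- if (tx$strand[1] == "+") "utr5" else "utr3"
      right_lab <- if (tx$strand[1] == "+") "utr3" else "utr5"
      for (i in seq_len(nrow(exons))) {
        a <- exons$start[i]; b <- min(exons$end[i], lo - 1)
        if (a <= b && hit(a, b)) labels <- c(labels, left_lab)
        a <- max(exons$start[i], hi + 1); b <- exons$end[i]
        if (a <= b && hit(a, b)) labels <- c(labels, right_lab)
      }
    } else {
      for (i in seq_len(nrow(exons))) {
        if (hit(exons$start[i], exons$end[i])) {
          labels <- c(labels, "noncoding_exon")
        }
      }
    }
    in_exon <- FALSE
    for (i in seq_len(nrow(exons))) {
      if (hit(exons$start[i], exons$end[i])) in_exon <- TRUE
    }
    if (length(labels) == 0 && hit(span_lo, span_hi)) {
      labels <- c(labels, "intron")
    }
    if (length(labels) > 0) {
      cand <- labels[which.max(sev[labels])]
      if (sev[cand] > sev[best]) best <- cand
    }
  }
  best
}

# O(n*m) overlap counter: rows (variant index, feature index).
oracle_overlap_pairs <- function(span, feat) {
  out <- list()
  for (i in seq_len(nrow(span))) {
    for (j in seq_len(nrow(feat))) {
      if (span$contig[i] == feat$contig[j] &&
          span$start[i] <= feat$end[j] && feat$start[j] <= span$end[i]) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(v = integer(), f = integer()))
  }
  m <- do.call(rbind, out)
  tibble(v = m[, 1], f = m[, 2])
}

# Hypergeometric upper tail by direct pmf summation.
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks) / choose(N, n))
}

# Greedy LD pruning re-derived by exhaustive enumeration: among all maximal
# conflict-free rsid subsets, the one reached by the stated priority order
# is the lexicographically first in priority indexing.
oracle_ld_prune <- function(info, ld_lookup, r2_max) {
  ord <- order(-info$n_studies, -info$n_samples, info$rsid)
  rsids <- info$rsid[ord]
  m <- length(rsids)
  subsets <- list()
  for (mask in seq_len(2^m) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    s <- rsids[idx]
    ok <- TRUE
    if (length(s) > 1) {
      for (a in seq_along(s)) {
        for (b in seq_along(s)) {
          if (a < b && ld_lookup(s[a], s[b]) > r2_max) ok <- FALSE
        }
      }
    }
    if (!ok) next
    maximal <- TRUE
    for (r in setdiff(rsids, s)) {
      conflict <- FALSE
      for (x in s) if (ld_lookup(r, x) > r2_max) conflict <- TRUE
      if (!conflict) maximal <- FALSE
    }
    if (maximal) subsets[[length(subsets) + 1]] <- sort(idx)
  }
  # lexicographically first maximal subset in priority indexing
  keyed <- vapply(subsets, function(s) {
    paste(sprintf("%03d", s), collapse = ",")
  }, character(1))
  rsids[subsets[[order(keyed)[1]]]]
}

# Direct per-codon translation via the genetic-code table (a lookup, not the
# package's translation path).
oracle_translate_codon <- function(codon, code = Biostrings::GENETIC_CODE) {
  unname(code[[toupper(codon)]])
}

tiny_reference <- function(seqs) {
  vapply(seqs, toupper, character(1))
}

# A hand-built plus/minus-strand transcript pair on a fixed sequence, used
# by the codon-effect tests. The CDS of txp is an explicit ORF.
fixture_single_exon_tx <- function(orf, pad5 = 10, pad3 = 8,
                                   strand = "+", contig = "ctg") {
  flank_l <- paste(rep("A", 20), collapse = "")
  flank_r <- paste(rep("T", 20), collapse = "")
  utr5 <- paste(rep("C", pad5), collapse = "")
  utr3 <- paste(rep("G", pad3), collapse = "")
  body <- if (strand == "+") {
    paste0(utr5, orf, utr3)
  } else {
    paste0(utr3, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(orf))), utr5)
  }
  seq <- paste0(flank_l, body, flank_r)
  exon_start <- 21L
  exon_end <- 20L + nchar(body)
  cds_start <- if (strand == "+") 21L + pad5 else 21L + pad3
  cds_end <- cds_start + nchar(orf) - 1L
  tx <- tibble(
    transcript_id = "tx1", gene_id = "g1", contig = contig,
    strand = strand,
    feature = c("exon", "CDS"),
    start = c(exon_start, cds_start),
    end = c(exon_end, cds_end)
  )
  list(reference = setNames(seq, contig), tx = tx,
       cds_start = cds_start, cds_end = cds_end)
}
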