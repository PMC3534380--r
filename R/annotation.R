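# Region classification and coding-consequence calling.
#
# Regions form a severity hierarchy: coding_exon > utr5 > utr3 >
# noncoding_exon > intron > intergenic. A variant overlapping several
# transcripts gets the most severe label; deletions are tested by the
# reference span they consume, insertions by their anchor base.

REGION_SEVERITY <- c(
  intergenic = 1, intron = 2, noncoding_exon = 3,
  utr3 = 4, utr5 = 5, coding_exon = 6
)

#' Decompose transcripts into labelled region intervals
#'
#' Expands each transcript into coding-exon, UTR, non-coding-exon and intron
#' intervals (1-based closed). UTRs are derived from the exon structure and
#' the CDS extent on the correct strand side, so transcripts read from
#' sources without explicit UTR records are handled identically; exons of a
#' transcript without any CDS are non-coding exons.
#'
#' @param transcripts Feature tibble (transcript_id, gene_id, contig,
#'   strand, feature, start, end).
#' @return Tibble (contig, start, end, region, transcript_id, gene_id).
#' @export
region_intervals <- function(transcripts) {
  purrr::map_dfr(split(transcripts, transcripts$transcript_id), function(tx) {
    exons <- tx %>% filter(.data$feature == "exon") %>% arrange(.data$start)
    cds <- tx %>% filter(.data$feature == "CDS") %>% arrange(.data$start)
    strand <- tx$strand[1]
    out <- list()
    add <- function(start, end, region) {
      keep <- start <= end
      if (any(keep)) {
        out[[length(out) + 1L]] <<- tibble(
          start = start[keep], end = end[keep], region = region
        )
      }
    }
    if (nrow(cds) == 0) {
      add(exons$start, exons$end, "noncoding_exon")
    } else {
      add(cds$start, cds$end, "coding_exon")
      cds_lo <- min(cds$start)
      cds_hi <- max(cds$end)
      # exon parts genomically left/right of the CDS; which is 5' depends
      # on strand
      left_lab <- if (strand == "+") "utr5" else "utr3"
      right_lab <- if (strand == "+") "utr3" else "utr5"
      add(exons$start, pmin(exons$end, cds_lo - 1L), left_lab)
      add(pmax(exons$start, cds_hi + 1L), exons$end, right_lab)
    }
    if (nrow(exons) > 1) {
      add(exons$end[-nrow(exons)] + 1L, exons$start[-1] - 1L, "intron")
    }
    bind_rows(out) %>%
      mutate(contig = tx$contig[1], transcript_id = tx$transcript_id[1],
             gene_id = tx$gene_id[1]) %>%
      select("contig", "start", "end", "region", "transcript_id", "gene_id")
  })
}

#' Classify variants by genomic region
#'
#' Assigns each variant exactly one of coding_exon, utr5, utr3,
#' noncoding_exon, intron or intergenic. Across overlapping transcripts the
#' most severe label wins (severity coding_exon > utr5 > utr3 >
#' noncoding_exon > intron > intergenic); ties go to the lexicographically
#' first transcript id. Variants touching no transcript are intergenic.
#'
#' @param variants Variant-call tibble.
#' @param transcripts Feature tibble as in [generate_genome_bundle()].
#' @return The input with `region` and `region_transcript_id` columns added.
#' @export
classify_region <- function(variants, transcripts) {
  n <- nrow(variants)
  region <- rep("intergenic", n)
  region_tx <- rep(NA_character_, n)
  if (n > 0 && nrow(transcripts) > 0) {
    iv <- region_intervals(transcripts)
    span <- variant_span(variants)
    for (ctg in unique(span$contig)) {
      vi <- which(span$contig == ctg)
      ji <- which(iv$contig == ctg)
      if (length(ji) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(span$start[vi], span$end[vi]),
        IRanges::IRanges(iv$start[ji], iv$end[ji])
      )
      if (length(hits) == 0) next
      h <- tibble(
        v = vi[S4Vectors::queryHits(hits)],
        region = iv$region[ji[S4Vectors::subjectHits(hits)]],
        tx = iv$transcript_id[ji[S4Vectors::subjectHits(hits)]]
      ) %>%
        mutate(sev = REGION_SEVERITY[.data$region]) %>%
        arrange(.data$v, desc(.data$sev), .data$tx) %>%
        distinct(.data$v, .keep_all = TRUE)
      region[h$v] <- h$region
      region_tx[h$v] <- h$tx
    }
  }
  mutate(variants, region = region, region_transcript_id = region_tx)
}

# 1-based index of genomic position `pos` within the spliced CDS of a
# transcript, counted in translation order. NA if pos is not in the CDS.
cds_index <- function(pos, cds_iv, strand) {
  iv <- cds_iv[order(cds_iv$start), , drop = FALSE]
  widths <- iv$end - iv$start + 1L
  total <- sum(widths)
  hit <- which(pos >= iv$start & pos <= iv$end)
  if (length(hit) == 0) return(NA_integer_)
  a <- as.integer(sum(widths[seq_len(hit - 1L)]) + (pos - iv$start[hit]) + 1L)
  if (strand == "+") a else total - a + 1L
}

complement_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

#' Coding consequence of a single-base substitution
#'
#' Builds the reference codon in transcript orientation (reverse-complement
#' on the minus strand), substitutes the alternate base and translates both
#' codons with the standard nuclear genetic code. An alternate codon that is
#' a stop yields `nonsense`; an unchanged amino acid `synonymous`; any other
#' change `missense`.
#'
#' @param variant One-row variant tibble (`vtype == "snp"`, position inside
#'   the transcript's CDS).
#' @param transcript Feature tibble of a single transcript.
#' @param reference Named character vector of contig sequences.
#' @return List: `effect`, `codon` (1-based codon index), `aa_ref`, `aa_alt`.
#' @export
coding_effect_snp <- function(variant, transcript, reference) {
  if (variant$vtype[1] != "snp") abort("`variant` must be a SNP")
  cds_iv <- transcript %>% filter(.data$feature == "CDS")
  if (nrow(cds_iv) == 0) abort("transcript has no CDS")
  strand <- transcript$strand[1]
  idx <- cds_index(variant$pos[1], cds_iv, strand)
  if (is.na(idx)) {
    abort("variant is not inside the CDS; use classify_region() first")
  }
  spliced <- spliced_sequence(reference[[variant$contig[1]]], cds_iv, strand)
  alt <- toupper(variant$alt[1])
  alt_t <- if (strand == "-") complement_base(alt) else alt

  codon_i <- (idx - 1L) %/% 3L
  within <- (idx - 1L) %% 3L
  ref_codon <- substr(spliced, 3L * codon_i + 1L, 3L * codon_i + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_t

  aa_ref <- translate_dna(ref_codon)
  aa_alt <- translate_dna(alt_codon)
  effect <- if (aa_alt == "*" && aa_ref != "*") {
    "nonsense"
  } else if (aa_alt == aa_ref) {
    "synonymous"
  } else {
    "missense"
  }
  list(effect = effect, codon = codon_i + 1L, aa_ref = aa_ref,
       aa_alt = aa_alt)
}

#' Coding consequence of an indel
#'
#' Counts the inserted or deleted bases that fall inside the CDS; a net
#' length change divisible by 3 is in-frame, anything else a frameshift.
#' The mutated spliced CDS is rebuilt (deleted in-CDS bases removed,
#' insertions spliced in at the anchor, reverse-complemented on the minus
#' strand) and translated from the start; the index of the first stop codon
#' is reported, which for a frameshift locates the premature stop. An indel
#' spanning a CDS boundary is flagged and its frame computed from the
#' in-CDS bases only.
#'
#' @param variant One-row variant tibble (`vtype == "indel"`, VCF-style
#'   anchored alleles).
#' @param transcript Feature tibble of a single transcript.
#' @param reference Named character vector of contig sequences.
#' @return List: `effect` (`inframe`/`frameshift`), `net_cds_change`,
#'   `stop_codon_at` (codon index of the first stop in the mutated CDS, NA
#'   if none), `premature_stop_at` (same, but NA unless it falls before the
#'   reference stop), `boundary` flag.
#' @export
coding_effect_indel <- function(variant, transcript, reference) {
  if (variant$vtype[1] != "indel") abort("`variant` must be an indel")
  cds_iv <- transcript %>% filter(.data$feature == "CDS") %>%
    arrange(.data$start)
  if (nrow(cds_iv) == 0) abort("transcript has no CDS")
  strand <- transcript$strand[1]
  seq <- reference[[variant$contig[1]]]
  spliced <- spliced_sequence(seq, cds_iv, strand)
  L <- nchar(spliced)

  ref_al <- toupper(variant$ref[1])
  alt_al <- toupper(variant$alt[1])
  pos <- variant$pos[1]

  if (nchar(ref_al) > nchar(alt_al)) { # deletion, anchored at pos
    deleted <- seq(pos + 1L, pos + nchar(ref_al) - 1L)
    in_cds <- vapply(deleted, function(p) {
      !is.na(cds_index(p, cds_iv, strand))
    }, logical(1))
    net <- -sum(in_cds)
    boundary <- any(in_cds) && !all(in_cds)
    idxs <- sort(vapply(deleted[in_cds], cds_index, integer(1),
                        cds_iv = cds_iv, strand = strand))
    mutated <- if (length(idxs)) {
      paste(strsplit(spliced, "")[[1]][-idxs], collapse = "")
    } else {
      spliced
    }
  } else {                             # insertion after the anchor base
    ins <- substr(alt_al, 2L, nchar(alt_al))
    a <- cds_index(pos, cds_iv, strand)
    if (is.na(a)) {
      abort("insertion anchor is not inside the CDS")
    }
    net <- nchar(ins)
    boundary <- FALSE
    mutated <- if (strand == "+") {
      paste0(substr(spliced, 1L, a), ins, substr(spliced, a + 1L, L))
    } else {
      paste0(substr(spliced, 1L, a - 1L), revcomp(ins),
             substr(spliced, a, L))
    }
  }

  effect <- if (net %% 3L == 0L) "inframe" else "frameshift"
  aa_mut <- translate_dna(mutated)
  stop_at <- as.integer(regexpr("*", aa_mut, fixed = TRUE))
  if (stop_at < 1L) stop_at <- NA_integer_
  aa_ref <- translate_dna(spliced)
  ref_stop <- as.integer(regexpr("*", aa_ref, fixed = TRUE))
  premature <- if (!is.na(stop_at) && (ref_stop < 1L || stop_at < ref_stop)) {
    stop_at
  } else {
    NA_integer_
  }
  list(effect = effect, net_cds_change = net, stop_codon_at = stop_at,
       premature_stop_at = premature, boundary = boundary)
}

#' Annotate variants with region, coding effect, repeat and regulatory context
#'
#' One-stop decoration of a variant table: region label (most severe across
#' transcripts), coding consequence for variants landing in a coding exon
#' (synonymous/missense/nonsense for SNPs, inframe/frameshift with the first
#' stop-codon index for indels), repeat class/family membership, and
#' regulatory context (TFBS restricted to 5-kb upstream windows, enhancers
#' genome-wide).
#'
#' @param variants Variant-call tibble.
#' @param bundle A `genome_bundle` (supplies transcripts, repeats,
#'   regulatory track and reference).
#' @param upstream_window Width of the gene upstream window for TFBS hits.
#' @return The input tibble with columns region, region_transcript_id,
#'   coding_effect, premature_stop_at, repeat_classes, regulatory_kinds.
#' @export
annotate_variants <- function(variants, bundle, upstream_window = 5000) {
  out <- classify_region(variants, bundle$transcripts)
  n <- nrow(out)
  effect <- rep("none", n)
  stop_at <- rep(NA_integer_, n)
  tx_split <- split(bundle$transcripts, bundle$transcripts$transcript_id)
  for (i in which(out$region == "coding_exon")) {
    tx <- tx_split[[out$region_transcript_id[i]]]
    v <- out[i, ]
    if (v$vtype == "snp") {
      eff <- coding_effect_snp(v, tx, bundle$reference)
      effect[i] <- eff$effect
    } else {
      cds_iv <- tx[tx$feature == "CDS", ]
      is_del <- nchar(v$ref) > nchar(v$alt)
      anchor_in <- !is.na(cds_index(v$pos, cds_iv, tx$strand[1]))
      if (is_del || anchor_in) {
        eff <- coding_effect_indel(v, tx, bundle$reference)
        effect[i] <- eff$effect
        stop_at[i] <- eff$premature_stop_at
      }
    }
  }
  out$coding_effect <- effect
  out$premature_stop_at <- stop_at

  rep_ov <- repeat_overlap(out, bundle$repeats)
  out$repeat_classes <- rep_ov$per_variant_classes
  reg_ov <- regulatory_overlap(out, bundle$regulatory, bundle$transcripts,
                               upstream_window = upstream_window)
  out$regulatory_kinds <- reg_ov$per_variant_kinds
  out
}
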