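# Repeat/regulatory track overlap, TSS metaprofiles and gene-set enrichment.

overlap_hits <- function(span, feat) {
  hits <- list(tibble(v = integer(), f = integer()))
  for (ctg in unique(span$contig)) {
    vi <- which(span$contig == ctg)
    fi <- which(feat$contig == ctg)
    if (length(fi) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(span$start[vi], span$end[vi]),
      IRanges::IRanges(feat$start[fi], feat$end[fi])
    )
    if (length(ov) == 0) next
    hits[[ctg]] <- tibble(
      v = vi[S4Vectors::queryHits(ov)],
      f = fi[S4Vectors::subjectHits(ov)]
    )
  }
  bind_rows(hits)
}

#' Overlap variants with the repeat track
#'
#' Counts variants falling in repeat features by repeat class and family.
#' A variant overlapping repeats of k distinct classes contributes once to
#' each class count but only once to the in-repeat denominator. Because the
#' natural denominator of per-class shares is ambiguous (variants in any
#' repeat, or all variants), both percentages are reported.
#'
#' @param variants Variant-call tibble.
#' @param repeats Repeat tibble (contig, start, end, name, class, family).
#' @return List: `n_variants`, `n_in_repeat`, `class_counts` (tibble class,
#'   n, pct_of_in_repeat, pct_of_all), `family_counts`, `per_variant_classes`
#'   (character vector, comma-collapsed classes per input variant).
#' @export
repeat_overlap <- function(variants, repeats) {
  n <- nrow(variants)
  per_variant <- rep(NA_character_, n)
  empty_counts <- tibble(class = character(), n = integer(),
                         pct_of_in_repeat = double(), pct_of_all = double())
  if (n == 0 || nrow(repeats) == 0) {
    return(list(
      n_variants = n, n_in_repeat = 0L,
      class_counts = empty_counts,
      family_counts = tibble(class = character(), family = character(),
                             n = integer()),
      per_variant_classes = per_variant
    ))
  }
  hits <- overlap_hits(variant_span(variants), repeats)
  if (nrow(hits) == 0) {
    return(list(
      n_variants = n, n_in_repeat = 0L, class_counts = empty_counts,
      family_counts = tibble(class = character(), family = character(),
                             n = integer()),
      per_variant_classes = per_variant
    ))
  }
  labelled <- hits %>%
    mutate(class = repeats$class[.data$f], family = repeats$family[.data$f])
  n_in_repeat <- dplyr::n_distinct(labelled$v)
  class_counts <- labelled %>%
    distinct(.data$v, .data$class) %>%
    count(.data$class, name = "n") %>%
    mutate(
      pct_of_in_repeat = round_half_up(100 * .data$n / n_in_repeat, 2),
      pct_of_all = round_half_up(100 * .data$n / !!n, 2)
    ) %>%
    arrange(desc(.data$n))
  family_counts <- labelled %>%
    distinct(.data$v, .data$class, .data$family) %>%
    count(.data$class, .data$family, name = "n") %>%
    arrange(desc(.data$n))
  collapsed <- labelled %>%
    distinct(.data$v, .data$class) %>%
    group_by(.data$v) %>%
    summarise(lab = paste(sort(.data$class), collapse = ","),
              .groups = "drop")
  per_variant[collapsed$v] <- collapsed$lab
  list(
    n_variants = n, n_in_repeat = n_in_repeat,
    class_counts = class_counts, family_counts = family_counts,
    per_variant_classes = per_variant
  )
}

#' Variant density profile around transcription start sites
#'
#' Counts variants in fixed-width bins around every TSS, in transcript
#' orientation: negative offsets are upstream of the TSS, positive
#' downstream, with minus-strand transcripts mirrored. The profile value is
#' the total count per bin divided by the number of transcripts, i.e. the
#' average per-transcript variant count in that bin.
#'
#' @param variants Variant-call tibble.
#' @param transcripts Feature tibble.
#' @param half_window Half-width of the window around the TSS (bases).
#' @param bin Bin width (must divide `half_window`).
#' @return A `tss_profile` tibble: bin_start, bin_mid, n, mean_per_transcript.
#' @export
tss_profile <- function(variants, transcripts, half_window = 2000, bin = 50) {
  if (half_window %% bin != 0) {
    abort("`half_window` must be a multiple of `bin`")
  }
  tss_tbl <- transcript_tss(transcripts)
  n_tx <- nrow(tss_tbl)
  bin_start <- seq(-half_window, half_window - bin, by = bin)
  prof <- tibble(
    bin_start = bin_start,
    bin_mid = bin_start + bin / 2,
    n = 0L
  )
  if (n_tx > 0 && nrow(variants) > 0) {
    rel <- purrr::map_dfr(seq_len(n_tx), function(i) {
      t <- tss_tbl[i, ]
      v <- variants[variants$contig == t$contig, ]
      r <- (v$pos - t$tss) * if (t$strand == "+") 1L else -1L
      tibble(rel = r[r >= -half_window & r < half_window])
    })
    if (nrow(rel) > 0) {
      k <- (rel$rel + half_window) %/% bin + 1L
      tab <- tabulate(k, nbins = nrow(prof))
      prof$n <- tab
    }
  }
  prof$mean_per_transcript <- if (n_tx > 0) prof$n / n_tx else NA_real_
  class(prof) <- c("tss_profile", class(prof))
  prof
}

#' Gene 5-kb upstream windows
#'
#' Strand-aware windows immediately upstream of each transcript's TSS
#' (excluding the TSS base itself), clamped at the contig start.
#'
#' @param transcripts Feature tibble.
#' @param width Window width in bases.
#' @return Tibble (contig, start, end, gene_id, transcript_id).
#' @export
upstream_windows <- function(transcripts, width = 5000) {
  tss_tbl <- transcript_tss(transcripts)
  tss_tbl %>%
    mutate(
      start = if_else(.data$strand == "+",
                      pmax(1L, as.integer(.data$tss - width)),
                      as.integer(.data$tss + 1L)),
      end = if_else(.data$strand == "+",
                    as.integer(.data$tss - 1L),
                    as.integer(.data$tss + width))
    ) %>%
    select("contig", "start", "end", "gene_id", "transcript_id")
}

#' Overlap variants with regulatory features
#'
#' Counts SNPs and indels inside TFBS features, restricted to hits that also
#' fall in some gene's upstream window, and inside enhancers genome-wide.
#'
#' @param variants Variant-call tibble.
#' @param features Regulatory tibble (contig, start, end, kind, label) with
#'   kind in `tfbs`/`enhancer`.
#' @param transcripts Feature tibble (supplies the upstream windows).
#' @param upstream_window Upstream window width in bases.
#' @return List: `counts` (tibble kind, vtype, n), `per_variant_kinds`
#'   (comma-collapsed kinds per input variant).
#' @export
regulatory_overlap <- function(variants, features, transcripts,
                               upstream_window = 5000) {
  n <- nrow(variants)
  per_variant <- rep(NA_character_, n)
  counts <- tidyr::expand_grid(kind = c("tfbs", "enhancer"),
                               vtype = c("snp", "indel")) %>%
    mutate(n = 0L)
  if (n == 0 || nrow(features) == 0) {
    return(list(counts = counts, per_variant_kinds = per_variant))
  }
  span <- variant_span(variants)
  hits <- overlap_hits(span, features)
  if (nrow(hits) > 0) {
    hits$kind <- features$kind[hits$f]
    # TFBS hits must additionally lie in an upstream window
    win <- upstream_windows(transcripts, width = upstream_window)
    in_win <- rep(TRUE, nrow(hits))
    tf <- which(hits$kind == "tfbs")
    if (length(tf) > 0) {
      wh <- overlap_hits(span[hits$v[tf], ], win)
      in_win[tf] <- seq_along(tf) %in% wh$v
    }
    hits <- hits[in_win, , drop = FALSE]
  }
  if (nrow(hits) > 0) {
    tallied <- hits %>%
      distinct(.data$v, .data$kind) %>%
      mutate(vtype = variants$vtype[.data$v]) %>%
      count(.data$kind, .data$vtype, name = "n")
    counts <- counts %>%
      rows_update_counts(tallied)
    collapsed <- hits %>%
      distinct(.data$v, .data$kind) %>%
      group_by(.data$v) %>%
      summarise(lab = paste(sort(.data$kind), collapse = ","),
                .groups = "drop")
    per_variant[collapsed$v] <- collapsed$lab
  }
  list(counts = counts, per_variant_kinds = per_variant)
}

rows_update_counts <- function(base, upd) {
  out <- left_join(base, upd, by = c("kind", "vtype"),
                   suffix = c("", ".new"))
  out$n <- ifelse(is.na(out$n.new), out$n, out$n.new)
  select(out, -"n.new")
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each gene set, the p-value is the hypergeometric upper tail
#' P(X >= k) of drawing k hit genes in a set of size K when n hits are drawn
#' from a universe of N genes; q-values are Benjamini-Hochberg adjusted and
#' a set is called enriched when q is at or below the FDR threshold. This is
#' a plain one-sided hypergeometric test, not the modified EASE-style score
#' some enrichment servers use.
#'
#' @param hit_genes Character vector of hit gene ids (subset of `universe`).
#' @param universe Character vector of all gene ids considered.
#' @param genesets Named list of character vectors.
#' @param fdr_threshold FDR threshold for the enriched flag.
#' @return Tibble: set, set_size, n_hits, p, q, enriched, ordered by p.
#' @export
geneset_enrichment <- function(hit_genes, universe, genesets,
                               fdr_threshold = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty gene universe")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe)) {
    abort("`hit_genes` must be a subset of `universe`")
  }
  N <- length(universe)
  n_draw <- length(hit_genes)
  res <- purrr::imap_dfr(genesets, function(set, name) {
    set <- intersect(unique(set), universe)
    K <- length(set)
    k <- length(intersect(hit_genes, set))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n_draw,
                                   lower.tail = FALSE)
    tibble(set = name, set_size = K, n_hits = k, p = p)
  })
  res %>%
    mutate(q = p.adjust(.data$p, method = "BH"),
           enriched = .data$q <= fdr_threshold) %>%
    arrange(.data$p)
}
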