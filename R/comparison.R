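# Cross-genome comparison: shared-site fractions against panel genomes and
# variant catalogs, novel-variant identification, and partition of novel
# variants by genomic context.

# Canonical site keys. Indels are left-normalised first so that equivalent
# representations (trailing shared bases, unstripped common suffixes) key
# identically; without this, representation differences inflate novelty.
catalog_keys <- function(catalog, allele_aware = TRUE) {
  norm <- normalise_variant(catalog)
  if (allele_aware) {
    # one key per alternate allele
    tidyr::separate_rows(norm, "alt", sep = ",") %>%
      mutate(key = paste(.data$contig, .data$pos, toupper(.data$alt),
                         sep = ":")) %>%
      pull(.data$key) %>%
      unique()
  } else {
    unique(paste(norm$contig, norm$pos, sep = ":"))
  }
}

#' Left-align and trim variant allele representations
#'
#' Removes shared trailing bases, then shared leading bases (keeping at
#' least one), adjusting the position, so that the same event is keyed
#' identically regardless of how a caller padded it.
#'
#' @param variants Tibble with contig, pos, ref, alt.
#' @return Tibble with normalised pos, ref, alt.
#' @export
normalise_variant <- function(variants) {
  out <- variants
  if (!"ref" %in% names(out) || !"alt" %in% names(out)) return(out)
  for (i in seq_len(nrow(out))) {
    if (grepl(",", out$alt[i], fixed = TRUE)) next # multi-allelic: leave
    r <- toupper(out$ref[i])
    a <- toupper(out$alt[i])
    p <- out$pos[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1L
    }
    out$ref[i] <- r
    out$alt[i] <- a
    out$pos[i] <- p
  }
  out
}

#' Fraction of subject variant sites shared with another catalog
#'
#' Sharing by default requires the same position and at least one common
#' alternate allele; with `allele_aware = FALSE` the same position alone
#' counts, which overstates identity but matches position-level published
#' comparisons. The percentage (of subject sites) is reported half-up to
#' two decimals.
#'
#' @param subject,other Variant catalogs (tibbles with contig, pos, ref, alt).
#' @param allele_aware Require a common alternate allele, not just position.
#' @return List: `n_subject`, `n_shared`, `pct`.
#' @export
shared_fraction <- function(subject, other, allele_aware = TRUE) {
  if (nrow(subject) == 0) abort("empty subject catalog")
  skey <- catalog_keys(subject, allele_aware)
  okey <- catalog_keys(other, allele_aware)
  if (allele_aware) {
    # shared at the site level: a subject site is shared if any of its
    # alternate alleles is present in the other catalog
    site_of <- sub(":[^:]*$", "", skey)
    shared_sites <- unique(site_of[skey %in% okey])
    n_subject <- dplyr::n_distinct(site_of)
    n_shared <- length(shared_sites)
  } else {
    n_subject <- length(skey)
    n_shared <- sum(skey %in% okey)
  }
  list(
    n_subject = n_subject,
    n_shared = n_shared,
    pct = round_half_up(100 * n_shared / n_subject, 2)
  )
}

#' Identify variants private to the subject
#'
#' A subject variant is novel when no panel genome and no catalog contains
#' it (same position and, by default, a common alternate allele).
#'
#' @param subject Subject catalog.
#' @param panels,catalogs Lists of catalogs to compare against.
#' @param allele_aware Passed to the sharing rule.
#' @return List: `novel` (tibble of novel subject rows), `n_novel`,
#'   `pct` (of subject sites, half-up to one decimal).
#' @export
novel_variants <- function(subject, panels = list(), catalogs = list(),
                           allele_aware = TRUE) {
  others <- c(panels, catalogs)
  if (length(others) == 0) abort("at least one comparison catalog required")
  other_keys <- unique(unlist(lapply(others, catalog_keys,
                                     allele_aware = allele_aware)))
  norm <- normalise_variant(subject)
  is_novel <- if (allele_aware) {
    # a site is shared when ANY of its alternate alleles is catalogued
    !purrr::map2_lgl(
      paste(norm$contig, norm$pos, sep = ":"),
      strsplit(toupper(norm$alt), ",", fixed = TRUE),
      function(site, alleles) any(paste(site, alleles, sep = ":") %in%
                                    other_keys)
    )
  } else {
    !(paste(norm$contig, norm$pos, sep = ":") %in% other_keys)
  }
  novel <- subject[is_novel, , drop = FALSE]
  list(
    novel = novel,
    n_novel = nrow(novel),
    pct = round_half_up(100 * nrow(novel) / nrow(subject), 1)
  )
}

#' Partition novel variants by gene and repeat context
#'
#' Labels each novel variant as gene-only, repeat-only, both or other,
#' according to overlap with gene spans (the full transcript extent) and
#' repeat features. The four labels are mutually exclusive and exhaustive,
#' so the counts sum to the novel total. Percentages are of the novel total,
#' half-up to two decimals; an empty novel set yields zero counts with
#' percentages reported as 0 and flagged undefined.
#'
#' @param novel Tibble of novel variants.
#' @param transcripts Feature tibble.
#' @param repeats Repeat tibble.
#' @return List: `counts` (tibble category, n, pct), `undefined` flag,
#'   `labels` (character vector per novel variant).
#' @export
partition_novel <- function(novel, transcripts, repeats) {
  cats <- c("gene_only", "repeat_only", "both", "other")
  if (nrow(novel) == 0) {
    return(list(
      counts = tibble(category = cats, n = 0L, pct = 0),
      undefined = TRUE,
      labels = character()
    ))
  }
  span <- variant_span(novel)
  gene_spans <- transcripts %>%
    group_by(.data$gene_id, .data$contig) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  in_gene <- rep(FALSE, nrow(novel))
  gh <- overlap_hits(span, gene_spans)
  in_gene[unique(gh$v)] <- TRUE
  in_rep <- rep(FALSE, nrow(novel))
  if (nrow(repeats) > 0) {
    rh <- overlap_hits(span, repeats)
    in_rep[unique(rh$v)] <- TRUE
  }
  labels <- dplyr::case_when(
    in_gene & in_rep ~ "both",
    in_gene ~ "gene_only",
    in_rep ~ "repeat_only",
    TRUE ~ "other"
  )
  counts <- tibble(category = cats) %>%
    left_join(tibble(category = labels) %>% count(.data$category, name = "n"),
              by = "category") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           pct = round_half_up(100 * .data$n / length(labels), 2))
  list(counts = counts, undefined = FALSE, labels = labels)
}
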