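# Mitochondrial genome comparison and variant classification on a circular
# reference: control / non-coding / RNA-gene / protein-coding regions, with
# synonymous vs non-synonymous calls under the vertebrate mitochondrial
# genetic code (TGA = Trp, AGA/AGG = stop).

mito_code <- function() Biostrings::getGeneticCode("SGC1")

# Positions covered by a possibly origin-wrapping 1-based region on a
# circular sequence of length n (start > end means the region wraps).
mt_region_positions <- function(start, end, n) {
  if (start <= end) seq(start, end) else c(seq(start, n), seq(1L, end))
}

#' Substitutions between a subject and reference mitochondrial sequence
#'
#' Coordinate-wise comparison of two equal-length sequences; no alignment is
#' performed, so indels are out of scope and a length mismatch is an error.
#'
#' @param subject_mt,reference_mt Character scalars (same length).
#' @return Tibble (pos, ref, alt), 1-based reference coordinates.
#' @export
mt_variants <- function(subject_mt, reference_mt) {
  if (nchar(subject_mt) != nchar(reference_mt)) {
    abort("subject and reference mt sequences differ in length; alignment is not performed")
  }
  s <- strsplit(toupper(subject_mt), "")[[1]]
  r <- strsplit(toupper(reference_mt), "")[[1]]
  d <- which(s != r)
  tibble(pos = d, ref = r[d], alt = s[d])
}

#' Classify mitochondrial variants by region and coding effect
#'
#' Assigns each substitution to one region category (control, noncoding,
#' rna, protein_coding); a position covered by several regions takes the
#' first covering region in table order. Variants in protein-coding regions
#' are translated with the vertebrate mitochondrial genetic code, reading
#' frame anchored at the region start (plus `frame` offset), and split into
#' synonymous and non-synonymous.
#'
#' @param variants Tibble (pos, ref, alt) from [mt_variants()].
#' @param regions Region tibble (start, end, category, strand, frame);
#'   `start > end` denotes a region wrapping the origin.
#' @param reference_mt The circular reference sequence.
#' @return List: `per_variant` (variants + category + effect),
#'   `category_counts` (tibble category, n), `n_synonymous`,
#'   `n_nonsynonymous`.
#' @export
mt_classify <- function(variants, regions, reference_mt) {
  n <- nchar(reference_mt)
  # category per position via the first covering region
  assign_region <- function(pos) {
    for (i in seq_len(nrow(regions))) {
      covered <- if (regions$start[i] <= regions$end[i]) {
        pos >= regions$start[i] & pos <= regions$end[i]
      } else {
        pos >= regions$start[i] | pos <= regions$end[i]
      }
      if (covered) return(i)
    }
    NA_integer_
  }
  ridx <- vapply(variants$pos, assign_region, integer(1))
  if (anyNA(ridx)) {
    abort(sprintf("position %d is not covered by any mt region",
                  variants$pos[which(is.na(ridx))[1]]))
  }
  category <- regions$category[ridx]

  effect <- rep(NA_character_, nrow(variants))
  code <- mito_code()
  for (i in which(category == "protein_coding")) {
    reg <- regions[ridx[i], ]
    posset <- mt_region_positions(reg$start, reg$end, n)
    offset <- match(variants$pos[i], posset) - 1L - reg$frame
    if (is.na(offset) || offset < 0) next
    codon_i <- offset %/% 3L
    within <- offset %% 3L
    codon_pos <- posset[reg$frame + codon_i * 3L + 1:3]
    if (anyNA(codon_pos)) next
    ref_codon <- paste(
      vapply(codon_pos, function(p) substr(reference_mt, p, p),
             character(1)),
      collapse = ""
    )
    strand <- reg$strand %||% "+"
    alt_codon <- ref_codon
    substr(alt_codon, within + 1L, within + 1L) <- toupper(variants$alt[i])
    if (identical(strand, "-")) {
      ref_codon <- revcomp(ref_codon)
      alt_codon <- revcomp(alt_codon)
    }
    aa_ref <- translate_dna(ref_codon, code)
    aa_alt <- translate_dna(alt_codon, code)
    effect[i] <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
  }

  per_variant <- mutate(variants, category = category, effect = effect)
  category_counts <- per_variant %>%
    count(.data$category, name = "n") %>%
    arrange(.data$category)
  list(
    per_variant = per_variant,
    category_counts = category_counts,
    n_synonymous = sum(effect == "synonymous", na.rm = TRUE),
    n_nonsynonymous = sum(effect == "nonsynonymous", na.rm = TRUE)
  )
}

#' Plant substitutions on a mitochondrial reference
#'
#' Builds a synthetic subject mitochondrial sequence carrying a prescribed
#' number of substitutions per region category and, within protein-coding
#' regions, a prescribed synonymous / non-synonymous split under the
#' vertebrate mitochondrial code. The planted truth is returned alongside
#' the sequence.
#'
#' @param bundle A `genome_bundle` (supplies `mt_reference`, `mt_regions`).
#' @param category_counts Named counts for categories
#'   (control, noncoding, rna, protein_coding).
#' @param n_synonymous Number of protein-coding substitutions that must be
#'   synonymous; the remainder are non-synonymous.
#' @param seed Integer seed.
#' @return List: `sequence` (subject mt), `truth` (tibble pos, ref, alt,
#'   category, effect).
#' @export
generate_mt_subject <- function(bundle,
                                category_counts = c(control = 9, noncoding = 1,
                                                    rna = 5,
                                                    protein_coding = 20),
                                n_synonymous = 16,
                                seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n_synonymous > category_counts[["protein_coding"]]) {
    abort("`n_synonymous` exceeds the protein-coding count")
  }
  ref <- bundle$mt_reference
  regions <- bundle$mt_regions
  n <- nchar(ref)
  code <- mito_code()

  with_seed(seed, {
    rows <- list()
    used <- integer()
    for (cat in names(category_counts)) {
      k <- category_counts[[cat]]
      if (k == 0) next
      reg_rows <- which(regions$category == cat)
      pool <- unlist(lapply(reg_rows, function(i) {
        mt_region_positions(regions$start[i], regions$end[i], n)
      }))
      # positions claimed by an earlier category (overlap-safe) or variant
      pool <- setdiff(unique(pool), used)
      if (cat != "protein_coding") {
        pos <- sample(pool, k)
        used <- c(used, pos)
        for (p in pos) {
          rb <- substr(ref, p, p)
          rows[[length(rows) + 1L]] <- tibble(
            pos = p, ref = rb,
            alt = sample(setdiff(c("A", "C", "G", "T"), rb), 1),
            category = cat, effect = NA_character_
          )
        }
      } else {
        wanted <- c(rep("synonymous", n_synonymous),
                    rep("nonsynonymous", k - n_synonymous))
        for (w in wanted) {
          found <- plant_mt_coding_variant(ref, regions, n, pool, w, code)
          pool <- setdiff(pool, found$pos)
          used <- c(used, found$pos)
          rows[[length(rows) + 1L]] <- tibble(
            pos = found$pos, ref = found$ref, alt = found$alt,
            category = cat, effect = w
          )
        }
      }
    }
    truth <- bind_rows(rows) %>% arrange(.data$pos)
    subject <- ref
    for (i in seq_len(nrow(truth))) {
      substr(subject, truth$pos[i], truth$pos[i]) <- truth$alt[i]
    }
    list(sequence = subject, truth = truth)
  })
}

# Search random protein-coding positions until a substitution with the
# wanted effect (synonymous / nonsynonymous) exists; returns pos/ref/alt.
plant_mt_coding_variant <- function(ref, regions, n, pool, wanted, code) {
  for (p in sample(pool, length(pool))) {
    reg_i <- which(regions$category == "protein_coding" &
                     vapply(seq_len(nrow(regions)), function(i) {
                       p %in% mt_region_positions(regions$start[i],
                                                  regions$end[i], n)
                     }, logical(1)))[1]
    reg <- regions[reg_i, ]
    posset <- mt_region_positions(reg$start, reg$end, n)
    offset <- match(p, posset) - 1L - reg$frame
    if (offset < 0) next
    codon_i <- offset %/% 3L
    within <- offset %% 3L
    codon_pos <- posset[reg$frame + codon_i * 3L + 1:3]
    if (anyNA(codon_pos)) next
    ref_codon <- paste(vapply(codon_pos, function(q) substr(ref, q, q),
                              character(1)), collapse = "")
    aa_ref <- translate_dna(ref_codon, code)
    rb <- substr(ref, p, p)
    for (alt in sample(setdiff(c("A", "C", "G", "T"), rb))) {
      alt_codon <- ref_codon
      substr(alt_codon, within + 1L, within + 1L) <- alt
      aa_alt <- translate_dna(alt_codon, code)
      effect <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
      if (effect == wanted) {
        return(list(pos = p, ref = rb, alt = alt))
      }
    }
  }
  abort(sprintf("could not plant a %s mt substitution", wanted))
}
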