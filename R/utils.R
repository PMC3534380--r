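# Shared helpers: rounding at printed precision, genotype normalisation,
# sequence arithmetic.

#' Round half away from zero at a fixed number of decimals
#'
#' Percentages and depths are reported at the precision a reader would print
#' them (one decimal for concordance, two for mean depth). Base `round()` uses
#' banker's rounding, so reported values use explicit half-up rounding instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(98.65, 1) # 98.7
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Normalise a genotype string to an unordered allele pair
#'
#' Genotypes are compared as unordered pairs: `"G/A"` and `"A/G"` are the same
#' call. Alleles are uppercased and sorted; separators `/` and `|` are both
#' accepted. Missing genotypes (`NA`, `"./."`, `"."`) return `NA`.
#'
#' @param gt Character vector of genotypes, e.g. `"A/G"`.
#' @return Character vector of canonical genotypes (sorted alleles joined by
#'   `/`), `NA` where missing.
#' @examples
#' normalise_genotype(c("G/A", "a|g", "./."))
#' @export
normalise_genotype <- function(gt) {
  out <- rep(NA_character_, length(gt))
  ok <- !is.na(gt) & gt != "./." & gt != "." & gt != ""
  if (any(ok)) {
    parts <- strsplit(toupper(gt[ok]), "[/|]")
    out[ok] <- vapply(
      parts,
      function(p) paste(sort(p), collapse = "/"),
      character(1)
    )
  }
  out
}

# Alleles of a normalised genotype as a list of character vectors.
genotype_alleles <- function(gt) {
  strsplit(normalise_genotype(gt), "/", fixed = TRUE)
}

is_heterozygous <- function(gt) {
  al <- genotype_alleles(gt)
  vapply(al, function(p) length(unique(p)) > 1, logical(1))
}

#' Reverse-complement a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate a DNA string with a given genetic code (default: standard nuclear).
# Returns the amino-acid string; incomplete trailing codons are dropped.
translate_dna <- function(x, code = Biostrings::GENETIC_CODE) {
  n <- nchar(x) - nchar(x) %% 3
  if (n == 0) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1, n)),
    genetic.code = code, no.init.codon = TRUE
  ))
}

# Extract the base at 1-based position `pos` of contig `contig` from a named
# character vector of sequences. Errors (naming the call) when out of bounds.
reference_base <- function(reference, contig, pos) {
  seqs <- reference[contig]
  if (anyNA(seqs)) {
    bad <- unique(contig[is.na(seqs)])
    abort(paste0("contig not in reference: ", paste(bad, collapse = ", ")))
  }
  too_far <- pos < 1 | pos > nchar(seqs)
  if (any(too_far)) {
    i <- which(too_far)[1]
    abort(sprintf(
      "position %d beyond length of contig %s (%d)",
      pos[i], contig[i], nchar(seqs[i])
    ))
  }
  substr(seqs, pos, pos)
}

# 1-based closed interval overlap between a point/span and interval vectors.
spans_overlap <- function(start1, end1, start2, end2) {
  start1 <= end2 & start2 <= end1
}

# Span a variant occupies on the reference: single base for SNPs and
# insertions (anchor base), the reference-consumed run for deletions.
variant_span <- function(variants) {
  ref_len <- nchar(variants$ref)
  tibble(
    contig = variants$contig,
    start = variants$pos,
    end = variants$pos + pmax(ref_len - 1L, 0L)
  )
}

# Deterministic local RNG: evaluates `expr` under the given seed without
# touching the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister")
}

# Concatenate the reference bases covered by 1-based closed `intervals`
# (tibble with start/end), ascending genomic order, then reverse-complement
# for minus-strand transcripts so the result reads in translation order.
spliced_sequence <- function(seq, intervals, strand) {
  iv <- intervals[order(intervals$start), , drop = FALSE]
  chunks <- substring(seq, iv$start, iv$end)
  s <- paste(chunks, collapse = "")
  if (strand == "-") revcomp(s) else s
}

# Inverse of spliced_sequence(): write `spliced` (given in translation order)
# back into `seq` across `intervals`. Returns the modified sequence.
write_spliced <- function(seq, intervals, strand, spliced) {
  iv <- intervals[order(intervals$start), , drop = FALSE]
  genomic <- if (strand == "-") revcomp(spliced) else spliced
  stopifnot(nchar(genomic) == sum(iv$end - iv$start + 1))
  off <- 0L
  for (i in seq_len(nrow(iv))) {
    w <- iv$end[i] - iv$start[i] + 1L
    substr(seq, iv$start[i], iv$end[i]) <- substr(genomic, off + 1L, off + w)
    off <- off + w
  }
  seq
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random open reading frame of `n_codons` codons: ATG start, non-stop body,
# stop at the end. Used to plant translatable CDSs in synthetic references.
random_orf <- function(n_codons, code = Biostrings::GENETIC_CODE) {
  stopifnot(n_codons >= 3)
  codons <- names(code)
  body <- codons[code != "*"]
  stops <- codons[code == "*"]
  paste(
    c("ATG", sample(body, n_codons - 2L, replace = TRUE), sample(stops, 1L)),
    collapse = ""
  )
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a fraction in [0, 1]", name))
  }
  invisible(x)
}
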