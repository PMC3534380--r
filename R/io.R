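# Readers and writers for the bundle's on-disk form: FASTA reference,
# VCF variant calls (GT, DP; QUAL column), GFF3 gene models, BED repeat and
# regulatory tracks, TSV risk tables and a JSON manifest. Writers format
# every field explicitly so that regenerating a bundle from the same seed
# reproduces byte-identical files. VCF/GFF are 1-based inclusive; BED is
# 0-based half-open; conversion happens here and nowhere else.

#' Write a genome bundle to a directory
#'
#' Emits `reference.fa`, `genes.gff3`, `repeats.bed` (BED6+2 with class and
#' family), `regulatory.bed` (BED6, kind in the name field), `mt.fa`,
#' `mt_regions.tsv` and `manifest.json`.
#'
#' @param bundle A `genome_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$reference),
    file.path(dir, "reference.fa")
  )
  write_gff3(bundle$transcripts, file.path(dir, "genes.gff3"))
  write_repeats_bed(bundle$repeats, file.path(dir, "repeats.bed"))
  write_regulatory_bed(bundle$regulatory, file.path(dir, "regulatory.bed"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrM = bundle$mt_reference)),
    file.path(dir, "mt.fa")
  )
  readr::write_tsv(bundle$mt_regions, file.path(dir, "mt_regions.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

write_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (tx in split(transcripts, transcripts$transcript_id)) {
    tid <- tx$transcript_id[1]
    gid <- tx$gene_id[1]
    ctg <- tx$contig[1]
    strand <- tx$strand[1]
    span <- c(min(tx$start), max(tx$end))
    lines <- c(
      lines,
      sprintf("%s\tpgint\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              ctg, span[1], span[2], strand, gid),
      sprintf("%s\tpgint\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              ctg, span[1], span[2], strand, tid, gid)
    )
    cds <- tx[tx$feature == "CDS", ]
    phases <- rep(".", nrow(tx))
    if (nrow(cds) > 0) {
      ord <- if (strand == "+") order(cds$start) else order(-cds$start)
      cum <- cumsum(c(0L, (cds$end - cds$start + 1L)[ord]))
      ph <- (3L - cum[-length(cum)] %% 3L) %% 3L
      phase_by_row <- integer(nrow(cds))
      phase_by_row[ord] <- ph
    }
    ci <- 0L
    for (i in seq_len(nrow(tx))) {
      phase <- "."
      if (tx$feature[i] == "CDS") {
        ci <- which(cds$start == tx$start[i] & cds$end == tx$end[i])[1]
        phase <- as.character(phase_by_row[ci])
      }
      lines <- c(lines, sprintf(
        "%s\tpgint\t%s\t%d\t%d\t.\t%s\t%s\tID=%s.%s%d;Parent=%s",
        ctg, tx$feature[i], tx$start[i], tx$end[i], strand, phase,
        tid, tolower(substr(tx$feature[i], 1, 1)), i, tid
      ))
    }
  }
  writeLines(lines, path)
}

#' Read gene models from a GFF3 file
#'
#' Parses exon, CDS and UTR records into the package's feature-long
#' transcript tibble. Transcript and gene ids come from the `Parent` chain
#' (`exon -> mRNA -> gene`).
#'
#' @param path GFF3 file.
#' @return Feature tibble (transcript_id, gene_id, contig, strand, feature,
#'   start, end).
#' @export
read_transcripts_gff3 <- function(path) {
  raw <- readr::read_tsv(
    path, comment = "#",
    col_names = c("contig", "source", "feature", "start", "end", "score",
                  "strand", "phase", "attributes"),
    col_types = "ccciicccc", progress = FALSE
  )
  attr_field <- function(x, key) {
    m <- stringr::str_match(x, paste0("(?:^|;)", key, "=([^;]+)"))
    m[, 2]
  }
  mrna <- raw %>%
    filter(.data$feature == "mRNA") %>%
    mutate(transcript_id = attr_field(.data$attributes, "ID"),
           gene_id = attr_field(.data$attributes, "Parent")) %>%
    select("transcript_id", "gene_id")
  raw %>%
    filter(.data$feature %in% c("exon", "CDS", "five_prime_UTR",
                                "three_prime_UTR")) %>%
    mutate(transcript_id = attr_field(.data$attributes, "Parent")) %>%
    left_join(mrna, by = "transcript_id") %>%
    select("transcript_id", "gene_id", "contig", "strand", "feature",
           "start", "end") %>%
    arrange(.data$transcript_id, .data$start, .data$feature)
}

write_repeats_bed <- function(repeats, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t%s",
                   repeats$contig, repeats$start - 1L, repeats$end,
                   repeats$name, repeats$class, repeats$family)
  writeLines(lines, path)
}

#' Read a BED6+2 repeat track
#' @param path BED file (chrom, start, end, name, score, strand, class,
#'   family).
#' @return Repeat tibble with 1-based closed coordinates.
#' @export
read_repeats_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("contig", "start0", "end", "name", "score", "strand",
                  "class", "family"),
    col_types = "ciiciccc", progress = FALSE
  )
  raw %>%
    mutate(start = .data$start0 + 1L) %>%
    select("contig", "start", "end", "name", "class", "family")
}

write_regulatory_bed <- function(regulatory, path) {
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t0\t.",
                   regulatory$contig, regulatory$start - 1L, regulatory$end,
                   regulatory$kind, regulatory$label)
  writeLines(lines, path)
}

#' Read a BED6 regulatory track (kind encoded in the name field)
#' @param path BED file with name `kind:label`.
#' @return Regulatory tibble with 1-based closed coordinates.
#' @export
read_regulatory_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("contig", "start0", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
  raw %>%
    mutate(
      start = .data$start0 + 1L,
      kind = sub(":.*$", "", .data$name),
      label = sub("^[^:]*:", "", .data$name)
    ) %>%
    select("contig", "start", "end", "kind", "label")
}

#' Write variant calls as VCF
#'
#' Single-sample VCF with GT and DP in the genotype column and the call
#' quality in QUAL. Genotype allele indices refer to the REF/ALT alleles of
#' the row.
#'
#' @param calls Variant-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgint",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"
  )
  gt_index <- function(gt, ref, alt) {
    alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
    idx <- match(strsplit(gt, "/", fixed = TRUE)[[1]], alleles) - 1L
    paste(sort(idx), collapse = "/")
  }
  body <- vapply(seq_len(nrow(calls)), function(i) {
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP\t%s:%d",
            calls$contig[i], calls$pos[i], calls$ref[i], calls$alt[i],
            format(calls$qual[i], nsmall = 1, trim = TRUE),
            gt_index(calls$genotype[i], calls$ref[i], calls$alt[i]),
            calls$depth[i])
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a single-sample VCF into a variant-call tibble
#'
#' Parses CHROM/POS/REF/ALT/QUAL plus GT and DP from the first sample
#' column; the genotype is resolved to allele strings and normalised to an
#' unordered pair. Rows whose REF and every ALT are single bases are SNPs,
#' anything else an indel.
#'
#' @param path VCF file.
#' @return Variant-call tibble.
#' @export
read_variant_calls <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), genotype = character(),
                  depth = integer(), qual = double(), vtype = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  fmt_split <- strsplit(vapply(f, `[`, character(1), 9), ":", fixed = TRUE)
  smp_split <- strsplit(vapply(f, `[`, character(1), 10), ":", fixed = TRUE)
  get_fmt <- function(i, key) {
    j <- match(key, fmt_split[[i]])
    if (is.na(j)) NA_character_ else smp_split[[i]][j]
  }
  n <- length(f)
  ref <- vapply(f, `[`, character(1), 4)
  alt <- vapply(f, `[`, character(1), 5)
  gt_raw <- vapply(seq_len(n), get_fmt, character(1), key = "GT")
  genotype <- vapply(seq_len(n), function(i) {
    alleles <- c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1]])
    idx <- strsplit(gt_raw[i], "[/|]")[[1]]
    if (any(idx == ".")) return(NA_character_)
    paste(sort(alleles[as.integer(idx) + 1L]), collapse = "/")
  }, character(1))
  tibble(
    contig = vapply(f, `[`, character(1), 1),
    pos = as.integer(vapply(f, `[`, character(1), 2)),
    ref = ref,
    alt = alt,
    genotype = genotype,
    depth = as.integer(vapply(seq_len(n), get_fmt, character(1), key = "DP")),
    qual = as.double(vapply(f, `[`, character(1), 6)),
    vtype = ifelse(
      nchar(ref) == 1 &
        vapply(strsplit(alt, ",", fixed = TRUE), function(a) {
          all(nchar(a) == 1)
        }, logical(1)),
      "snp", "indel"
    )
  )
}

#' Write a risk bundle's tables to a directory
#'
#' Emits `associations.tsv` (rsid, chrom, pos, disease, genotype, LR,
#' n_studies, n_samples), `ld.tsv`, `prevalence.tsv`, `panel.tsv`,
#' `subject_genotypes.tsv`, `pgx.tsv` and `risk_manifest.json`.
#'
#' @param bundle A `risk_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_risk_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  assoc <- bundle$associations %>%
    select(rsid = "rsid", chrom = "contig", pos = "pos",
           disease = "disease", genotype = "genotype", LR = "lr",
           n_studies = "n_studies", n_samples = "n_samples")
  readr::write_tsv(assoc, file.path(dir, "associations.tsv"))
  readr::write_tsv(bundle$ld, file.path(dir, "ld.tsv"))
  readr::write_tsv(bundle$prevalence, file.path(dir, "prevalence.tsv"))
  readr::write_tsv(bundle$panel, file.path(dir, "panel.tsv"))
  readr::write_tsv(bundle$subject_genotypes,
                   file.path(dir, "subject_genotypes.tsv"))
  readr::write_tsv(bundle$pgx, file.path(dir, "pgx.tsv"))
  manifest <- bundle$manifest
  manifest$model <- NULL # generative tables stay in memory, counts on disk
  jsonlite::write_json(manifest, file.path(dir, "risk_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a risk bundle written by [write_risk_bundle()]
#' @param dir Directory holding the TSV tables.
#' @return A `risk_bundle` list (without the in-memory generative model).
#' @export
read_risk_bundle <- function(dir) {
  assoc <- readr::read_tsv(file.path(dir, "associations.tsv"),
                           col_types = "cciccdii", progress = FALSE) %>%
    select(rsid = "rsid", contig = "chrom", pos = "pos",
           disease = "disease", genotype = "genotype", lr = "LR",
           n_studies = "n_studies", n_samples = "n_samples")
  structure(
    list(
      associations = assoc,
      ld = readr::read_tsv(file.path(dir, "ld.tsv"), col_types = "ccd",
                           progress = FALSE),
      prevalence = readr::read_tsv(file.path(dir, "prevalence.tsv"),
                                   col_types = "ciiccd", progress = FALSE),
      panel = readr::read_tsv(file.path(dir, "panel.tsv"),
                              col_types = "ccc", progress = FALSE),
      subject_genotypes = readr::read_tsv(
        file.path(dir, "subject_genotypes.tsv"), col_types = "cc",
        progress = FALSE),
      pgx = readr::read_tsv(file.path(dir, "pgx.tsv"), col_types = "ccccc",
                            progress = FALSE),
      manifest = jsonlite::read_json(file.path(dir, "risk_manifest.json"))
    ),
    class = "risk_bundle"
  )
}

#' Write array genotypes as TSV
#' @param array_genotypes Tibble (contig, pos, genotype).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_array_genotypes <- function(array_genotypes, path) {
  out <- array_genotypes %>%
    mutate(rsid = ".", .before = 1) %>%
    select("rsid", chrom = "contig", pos = "pos", genotype = "genotype")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read array genotypes written by [write_array_genotypes()]
#' @param path TSV path.
#' @return Tibble (contig, pos, genotype).
#' @export
read_array_genotypes <- function(path) {
  readr::read_tsv(path, col_types = "ccic", progress = FALSE) %>%
    select(contig = "chrom", pos = "pos", genotype = "genotype")
}
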