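# Synthetic variant calls, array genotypes and per-base depth tracks with
# planted pass/fail status against the pipeline's filter rules.

# Negative-binomial (gamma-Poisson) depth draw: mean `mu`, variance
# mu + overdispersion * mu^2, i.e. heavier in both tails than Poisson.
rdepth <- function(n, mu, overdispersion) {
  if (overdispersion <= 0) return(stats::rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / overdispersion)
}

# Rejection-sample depths into (or out of) [lo, hi].
rdepth_within <- function(n, mu, overdispersion, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    d <- rdepth(2L * n + 50L, mu, overdispersion)
    out <- c(out, d[d >= lo & d <= hi])
  }
  out[seq_len(n)]
}

#' Generate synthetic variant calls with planted filter status
#'
#' Plants `n_snp` substitutions and `n_indel` short indels on a synthetic
#' genome bundle. A fixed fraction is placed inside exons (the rest strictly
#' outside), read depth follows a gamma-Poisson model whose variance exceeds
#' its mean, and a configurable fraction of calls is planted to fail each
#' quality-control rule: depth outside `[depth_min, depth_max]`, quality
#' below `qual_min`, or a heterozygous genotype sharing no allele with the
#' reference. The planted status of every call, and the category counts, are
#' recorded (columns `planted_status`, `planted_exonic`; manifest in
#' `attr(, "manifest")`) so filters can be tested against ground truth.
#'
#' @param bundle A `genome_bundle` from [generate_genome_bundle()].
#' @param n_snp,n_indel Number of substitutions / indels to plant.
#' @param depth_mean Mean read depth.
#' @param depth_overdispersion Gamma-Poisson overdispersion (0 = Poisson).
#' @param exonic_fraction Fraction of SNPs planted inside exons.
#' @param indel_exonic_fraction Fraction of indels planted inside exons.
#' @param het_fraction Fraction of passing calls that are heterozygous.
#' @param frac_fail_depth,frac_fail_qual,frac_het_no_ref Planted failure
#'   fractions for the three filter rules.
#' @param depth_min,depth_max,qual_min Filter thresholds the planting targets.
#' @param seed Integer seed.
#' @return Tibble of calls (contig, pos, ref, alt, genotype, depth, qual,
#'   vtype, planted_status, planted_exonic) with a `manifest` attribute.
#' @export
generate_variant_calls <- function(bundle,
                                   n_snp = 2000,
                                   n_indel = 200,
                                   depth_mean = 34.94,
                                   depth_overdispersion = 0.15,
                                   exonic_fraction = 0.056,
                                   indel_exonic_fraction = 0.041,
                                   het_fraction = 0.603,
                                   frac_fail_depth = 0.02,
                                   frac_fail_qual = 0.015,
                                   frac_het_no_ref = 0.01,
                                   depth_min = 5, depth_max = 60,
                                   qual_min = 30,
                                   seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n_snp < 0 || n_indel < 0) abort("variant counts must be non-negative")
  if (depth_mean <= 0) abort("`depth_mean` must be > 0")
  for (nm in c("exonic_fraction", "indel_exonic_fraction", "het_fraction",
               "frac_fail_depth", "frac_fail_qual", "frac_het_no_ref")) {
    assert_fraction(get(nm), nm)
  }

  with_seed(seed, {
    exon_pool <- exon_position_pool(bundle)
    calls <- bind_rows(
      plant_calls(bundle, n_snp, "snp", exonic_fraction, exon_pool,
                  het_fraction, frac_fail_depth, frac_fail_qual,
                  frac_het_no_ref, depth_mean, depth_overdispersion,
                  depth_min, depth_max, qual_min),
      plant_calls(bundle, n_indel, "indel", indel_exonic_fraction, exon_pool,
                  het_fraction, frac_fail_depth, frac_fail_qual,
                  0, depth_mean, depth_overdispersion,
                  depth_min, depth_max, qual_min)
    )
    if (nrow(calls) > 0) calls <- arrange(calls, .data$contig, .data$pos)

    manifest <- list(
      seed = seed,
      n_snp = sum(calls$vtype == "snp"),
      n_indel = sum(calls$vtype == "indel"),
      n_pass = sum(calls$planted_status == "pass"),
      n_fail_depth = sum(calls$planted_status == "fail_depth"),
      n_fail_quality = sum(calls$planted_status == "fail_quality"),
      n_fail_het_no_ref = sum(calls$planted_status == "fail_het_no_ref"),
      n_exonic_snp = sum(calls$planted_exonic & calls$vtype == "snp"),
      n_exonic_indel = sum(calls$planted_exonic & calls$vtype == "indel"),
      depth_mean = depth_mean,
      depth_overdispersion = depth_overdispersion,
      thresholds = list(depth_min = depth_min, depth_max = depth_max,
                        qual_min = qual_min)
    )
    attr(calls, "manifest") <- manifest
    calls
  })
}

# (contig, pos) pairs covered by at least one exon
exon_position_pool <- function(bundle) {
  ex <- filter(bundle$transcripts, .data$feature == "exon")
  if (nrow(ex) == 0) return(tibble(contig = character(), pos = integer()))
  purrr::map_dfr(seq_len(nrow(ex)), function(i) {
    tibble(contig = ex$contig[i], pos = seq(ex$start[i], ex$end[i]))
  }) %>% distinct()
}

plant_calls <- function(bundle, n, vtype, exonic_fraction, exon_pool,
                        het_fraction, frac_fail_depth, frac_fail_qual,
                        frac_het_no_ref, depth_mean, depth_overdispersion,
                        depth_min, depth_max, qual_min) {
  empty <- tibble(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), genotype = character(), depth = integer(),
    qual = double(), vtype = character(), planted_status = character(),
    planted_exonic = logical()
  )
  if (n == 0) return(empty)

  n_ex <- round(n * exonic_fraction)
  n_ex <- min(n_ex, nrow(exon_pool))
  positions <- bind_rows(
    if (n_ex > 0) {
      mutate(exon_pool[sample(nrow(exon_pool), n_ex), ], planted_exonic = TRUE)
    },
    sample_nonexonic(bundle, n - n_ex, exon_pool) %>%
      mutate(planted_exonic = FALSE)
  )

  status <- sample(c(
    rep("fail_depth", round(n * frac_fail_depth)),
    rep("fail_quality", round(n * frac_fail_qual)),
    rep("fail_het_no_ref", round(n * frac_het_no_ref)),
    rep("pass", n - round(n * frac_fail_depth) - round(n * frac_fail_qual) -
          round(n * frac_het_no_ref))
  ))

  depth <- integer(n)
  ok <- status != "fail_depth"
  depth[ok] <- rdepth_within(sum(ok), depth_mean, depth_overdispersion,
                             depth_min, depth_max)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    low <- rbinom(n_bad, 1, 0.5) == 1
    depth[!ok] <- ifelse(low, sample(0:(depth_min - 1), n_bad, replace = TRUE),
                         sample((depth_max + 1):(2 * depth_max), n_bad,
                                replace = TRUE))
  }
  qual <- ifelse(status == "fail_quality",
                 runif(n, 5, qual_min - 0.1),
                 runif(n, qual_min, 60))
  qual <- round(qual, 1)

  alleles <- purrr::map(seq_len(n), function(i) {
    make_alleles(bundle, positions$contig[i], positions$pos[i], vtype,
                 status[i], het_fraction)
  })

  tibble(
    contig = positions$contig,
    pos = positions$pos,
    ref = purrr::map_chr(alleles, "ref"),
    alt = purrr::map_chr(alleles, "alt"),
    genotype = purrr::map_chr(alleles, "genotype"),
    depth = depth,
    qual = qual,
    vtype = vtype,
    planted_status = status,
    planted_exonic = positions$planted_exonic
  )
}

sample_nonexonic <- function(bundle, n, exon_pool) {
  if (n == 0) return(tibble(contig = character(), pos = integer()))
  lens <- vapply(bundle$reference, nchar, integer(1))
  out <- tibble(contig = character(), pos = integer())
  while (nrow(out) < n) {
    ctg <- sample(names(lens), 2L * n, replace = TRUE,
                  prob = lens / sum(lens))
    # keep a 10-base tail margin so deletion spans stay on the contig
    pos <- unname(vapply(ctg, function(cc) {
      sample(seq_len(lens[[cc]] - 10L), 1)
    }, integer(1)))
    cand <- distinct(tibble(contig = ctg, pos = pos)) %>%
      anti_join(exon_pool, by = c("contig", "pos"))
    out <- distinct(bind_rows(out, cand))
  }
  out[seq_len(n), ]
}

make_alleles <- function(bundle, contig, pos, vtype, status, het_fraction) {
  bases <- c("A", "C", "G", "T")
  refbase <- reference_base(bundle$reference, contig, pos)
  if (vtype == "snp") {
    if (status == "fail_het_no_ref") {
      alts <- sample(setdiff(bases, refbase), 2)
      return(list(ref = refbase, alt = paste(alts, collapse = ","),
                  genotype = paste(sort(alts), collapse = "/")))
    }
    alt <- sample(setdiff(bases, refbase), 1)
    gt <- if (runif(1) < het_fraction) c(refbase, alt) else c(alt, alt)
    list(ref = refbase, alt = alt,
         genotype = paste(sort(gt), collapse = "/"))
  } else {
    if (runif(1) < 0.5) { # deletion
      dlen <- sample(1:6, 1)
      ref <- substr(bundle$reference[[contig]], pos, pos + dlen)
      alt <- refbase
    } else {              # insertion
      ilen <- sample(1:6, 1)
      ref <- refbase
      alt <- paste0(refbase, paste(sample(bases, ilen, replace = TRUE),
                                   collapse = ""))
    }
    gt <- if (runif(1) < het_fraction) c(ref, alt) else c(alt, alt)
    list(ref = ref, alt = alt, genotype = paste(sort(gt), collapse = "/"))
  }
}

#' Generate array genotypes with a planted discordance rate
#'
#' Copies the genotypes of the SNP calls and perturbs each site
#' independently with probability `discordance_rate`, emulating the
#' genotyping-array comparison used to validate sequencing calls. The
#' realised number of discordant sites is recorded in the manifest
#' attribute.
#'
#' @param calls Variant-call tibble (only `vtype == "snp"` rows are used).
#' @param discordance_rate Per-site probability of a discordant array call.
#' @param seed Integer seed.
#' @return Tibble (contig, pos, genotype) with a `manifest` attribute
#'   holding `discordance_rate` and `n_discordant`.
#' @export
generate_array_genotypes <- function(calls, discordance_rate = 0.013, seed) {
  if (missing(seed)) abort("`seed` is required")
  assert_fraction(discordance_rate, "discordance_rate")
  snps <- filter(calls, .data$vtype == "snp")
  with_seed(seed, {
    flip <- runif(nrow(snps)) < discordance_rate
    gt <- normalise_genotype(snps$genotype)
    gt[flip] <- vapply(which(flip), function(i) {
      perturb_genotype(gt[i])
    }, character(1))
    out <- tibble(contig = snps$contig, pos = snps$pos, genotype = gt)
    attr(out, "manifest") <- list(
      discordance_rate = discordance_rate,
      n_sites = nrow(out),
      n_discordant = sum(flip)
    )
    out
  })
}

# Replace one allele with a different base so the normalised genotype changes.
perturb_genotype <- function(gt) {
  al <- strsplit(gt, "/", fixed = TRUE)[[1]]
  repeat {
    i <- sample(length(al), 1)
    new <- sample(setdiff(c("A", "C", "G", "T"), al[i]), 1)
    cand <- paste(sort(replace(al, i, new)), collapse = "/")
    if (cand != gt) return(cand)
  }
}

#' Generate comparison catalogs with a planted novel fraction
#'
#' Splits the subject's SNP sites into a planted-novel set (present in no
#' catalog) and a shared set; every shared site is placed in at least one
#' catalog and independently in each further catalog with probability
#' `share`. Catalogs also receive decoy sites absent from the subject. The
#' planted novel keys are recorded in the manifest attribute.
#'
#' @param calls Variant-call tibble (SNP rows are used).
#' @param bundle The `genome_bundle` the calls were planted on (supplies
#'   contig bounds for decoy sites).
#' @param n_catalogs Number of catalogs.
#' @param share Probability a shared site enters each additional catalog.
#' @param novel_fraction Fraction of subject sites private to the subject.
#' @param n_decoys Decoy sites per catalog.
#' @param seed Integer seed.
#' @return List of catalog tibbles (contig, pos, ref, alt); attribute
#'   `manifest` records the planted novel site keys.
#' @export
generate_panel_catalogs <- function(calls, bundle, n_catalogs = 3,
                                    share = 0.5, novel_fraction = 0.1,
                                    n_decoys = 200, seed) {
  if (missing(seed)) abort("`seed` is required")
  assert_fraction(share, "share")
  assert_fraction(novel_fraction, "novel_fraction")
  snps <- filter(calls, .data$vtype == "snp")
  with_seed(seed, {
    n <- nrow(snps)
    n_novel <- round(n * novel_fraction)
    novel_idx <- sample(n, n_novel)
    shared_idx <- setdiff(seq_len(n), novel_idx)
    anchor <- sample(n_catalogs, length(shared_idx), replace = TRUE)
    catalogs <- lapply(seq_len(n_catalogs), function(k) {
      extra <- shared_idx[anchor != k &
                            runif(length(shared_idx)) < share]
      own <- sort(unique(c(shared_idx[anchor == k], extra)))
      decoys <- random_decoy_sites(bundle, n_decoys, snps)
      bind_rows(
        select(snps[own, ], "contig", "pos", "ref", "alt"),
        decoys
      ) %>% arrange(.data$contig, .data$pos)
    })
    attr(catalogs, "manifest") <- list(
      novel_fraction = novel_fraction,
      n_novel = n_novel,
      novel_keys = paste(snps$contig[novel_idx], snps$pos[novel_idx],
                         sep = ":")
    )
    catalogs
  })
}

random_decoy_sites <- function(bundle, n, snps) {
  if (n == 0) {
    return(tibble(contig = character(), pos = integer(),
                  ref = character(), alt = character()))
  }
  lens <- vapply(bundle$reference, nchar, integer(1))
  taken <- paste(snps$contig, snps$pos, sep = ":")
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    ctg <- sample(names(lens), 2L * n, replace = TRUE,
                  prob = lens / sum(lens))
    pos <- unname(vapply(ctg, function(cc) sample(lens[[cc]], 1),
                         integer(1)))
    cand <- distinct(tibble(contig = ctg, pos = pos)) %>%
      filter(!paste(.data$contig, .data$pos, sep = ":") %in% taken)
    out <- distinct(bind_rows(out, cand))
  }
  out <- out[seq_len(n), ]
  refbase <- reference_base(bundle$reference, out$contig, out$pos)
  alt <- vapply(refbase, function(rb) {
    sample(setdiff(c("A", "C", "G", "T"), rb), 1)
  }, character(1))
  mutate(out, ref = unname(refbase), alt = unname(alt))
}

#' Simulate a per-base depth track for a genome bundle
#'
#' Draws an independent gamma-Poisson depth for every reference base,
#' reproducing a coverage distribution with more weight in both tails than
#' the Poisson of the same mean.
#'
#' @param bundle A `genome_bundle`.
#' @param depth_mean Mean depth.
#' @param depth_overdispersion Gamma-Poisson overdispersion (0 = Poisson).
#' @param seed Integer seed.
#' @return Named list of integer vectors, one per contig.
#' @export
generate_depth_track <- function(bundle, depth_mean = 34.94,
                                 depth_overdispersion = 0.15, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (depth_mean <= 0) abort("`depth_mean` must be > 0")
  with_seed(seed, {
    lapply(bundle$reference, function(s) {
      rdepth(nchar(s), depth_mean, depth_overdispersion)
    })
  })
}
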