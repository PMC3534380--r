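# Summary statistics and pipeline orchestration.

#' Printed-precision sequencing summary arithmetic
#'
#' Small helpers that reproduce the arithmetic behind the headline
#' sequencing statistics: mean mapped depth as mapped bases over non-N
#' reference bases (two decimals), total raw gigabases as read count times
#' read length with Gb meaning 1e9 bases (two decimals), and mean assembly
#' contig length as total assembled bases over contig count (whole bases).
#' All use half-up rounding at the printed precision.
#'
#' @param mapped_bases,non_n_bases Total mapped bases and non-N reference
#'   length.
#' @return Mean depth, two decimals.
#' @examples
#' mean_mapped_depth(99.97e9, 2861343702) # 34.94
#' @export
mean_mapped_depth <- function(mapped_bases, non_n_bases) {
  if (non_n_bases <= 0) abort("`non_n_bases` must be positive")
  round_half_up(mapped_bases / non_n_bases, 2)
}

#' @rdname mean_mapped_depth
#' @param n_reads,read_length Read count and uniform read length.
#' @export
total_raw_gb <- function(n_reads, read_length) {
  round_half_up(n_reads * read_length / 1e9, 2)
}

#' @rdname mean_mapped_depth
#' @param total_bases,n_contigs Assembled bases and contig count.
#' @export
mean_contig_length <- function(total_bases, n_contigs) {
  if (n_contigs <= 0) abort("`n_contigs` must be positive")
  round_half_up(total_bases / n_contigs, 0)
}

#' Key-value summary of a pipeline run
#'
#' Collects the headline numbers of the filter, coverage and comparison
#' stages into a single key-value tibble at printed precision. A missing
#' upstream report is an error naming the stage.
#'
#' @param filter_report A `filter_report` (depth/quality/het rules merged
#'   upstream or a single report).
#' @param coverage A `coverage_profile`.
#' @param comparison Output of [novel_variants()] (optionally with a `pct`
#'   from [array_concordance()] supplied via `concordance`).
#' @param concordance Optional output of [array_concordance()].
#' @return Tibble (metric, value).
#' @export
summary_table <- function(filter_report = NULL, coverage = NULL,
                          comparison = NULL, concordance = NULL) {
  if (is.null(filter_report)) abort("missing upstream report: variant filter")
  if (is.null(coverage)) abort("missing upstream report: coverage")
  if (is.null(comparison)) abort("missing upstream report: comparison")
  pass <- filter_report$pass_set
  n_snp <- sum(pass$vtype == "snp")
  n_indel <- sum(pass$vtype == "indel")
  rows <- tibble(
    metric = c(
      "Total variant calls", "Pass filters", "Total SNPs", "Total indels",
      "Fail depth", "Fail quality", "Fail het-no-ref",
      "Mean mapped depth (x)", "Bases accessed (% of genome)",
      "Bases at >=5 reads (% of genome)",
      "Novel variants", "Novel variants (% of subject)"
    ),
    value = c(
      filter_report$n_input, filter_report$n_pass, n_snp, n_indel,
      filter_report$n_fail_depth, filter_report$n_fail_quality,
      filter_report$n_fail_het_no_ref,
      round_half_up(coverage$mean_depth, 2),
      round_half_up(100 * coverage$frac_ge1, 2),
      round_half_up(100 * coverage$frac_ge5, 2),
      comparison$n_novel, comparison$pct
    )
  )
  if (!is.null(concordance)) {
    rows <- bind_rows(rows, tibble(
      metric = c("Array sites compared", "Array concordance (%)"),
      value = c(concordance$n_sites, concordance$pct)
    ))
  }
  rows
}

#' Default pipeline configuration
#'
#' @param seed Integer seed driving every synthetic input.
#' @param out_dir Output directory for stage artifacts.
#' @param overrides Named list merged over the defaults.
#' @return A validated config list.
#' @export
pipeline_config <- function(seed, out_dir, overrides = list()) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    depth_min = 5, depth_max = 60, qual_min = 30,
    mito_contig = "chrM",
    r2_max = 0.3, fdr = 0.05,
    window = 50000, tss_half_window = 2000, tss_bin = 50,
    upstream_window = 5000,
    n_snp = 2000, n_indel = 200,
    depth_mean = 34.94, depth_overdispersion = 0.15,
    discordance_rate = 0.013,
    novel_fraction = 0.1,
    n_diseases = 3, snps_per_disease = 6, panel_size = 101
  )
  cfg <- modifyList(cfg, overrides)
  if (cfg$depth_min > cfg$depth_max) {
    abort("invalid config: depth_min > depth_max")
  }
  if (cfg$qual_min < 0 || cfg$r2_max < 0 || cfg$r2_max > 1 ||
      cfg$fdr < 0 || cfg$fdr > 1) {
    abort("invalid config: thresholds out of range")
  }
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full synthetic-genome interpretation pipeline
#'
#' Stages run in order: simulate (all synthetic inputs written to disk),
#' qc (filters, concordance, coverage), annotate, compare, risk, mtdna,
#' summary. Every artifact is written under `config$out_dir`; the run is a
#' deterministic function of `config$seed`, so re-running with the same
#' config reproduces byte-identical files.
#'
#' @param config A config list from [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config$seed, config$out_dir,
                         config[setdiff(names(config),
                                        c("seed", "out_dir"))])
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- run_stage("simulate", {
    bundle <- generate_genome_bundle(seed = cfg$seed)
    calls <- generate_variant_calls(
      bundle, n_snp = cfg$n_snp, n_indel = cfg$n_indel,
      depth_mean = cfg$depth_mean,
      depth_overdispersion = cfg$depth_overdispersion,
      seed = cfg$seed + 1L
    )
    array_gt <- generate_array_genotypes(
      calls, discordance_rate = cfg$discordance_rate, seed = cfg$seed + 2L
    )
    depths <- generate_depth_track(
      bundle, depth_mean = cfg$depth_mean,
      depth_overdispersion = cfg$depth_overdispersion, seed = cfg$seed + 3L
    )
    catalogs <- generate_panel_catalogs(
      calls, bundle, novel_fraction = cfg$novel_fraction,
      seed = cfg$seed + 4L
    )
    risk <- generate_risk_bundle(
      n_diseases = cfg$n_diseases, snps_per_disease = cfg$snps_per_disease,
      panel_size = cfg$panel_size, seed = cfg$seed + 5L
    )
    mt_subject <- generate_mt_subject(bundle, seed = cfg$seed + 6L)
    input_dir <- file.path(cfg$out_dir, "inputs")
    write_genome_bundle(bundle, input_dir)
    write_variant_calls(calls, file.path(input_dir, "calls.vcf"))
    write_array_genotypes(array_gt, file.path(input_dir, "array.tsv"))
    write_risk_bundle(risk, input_dir)
    list(bundle = bundle, calls = calls, array_gt = array_gt,
         depths = depths, catalogs = catalogs, risk = risk,
         mt_subject = mt_subject)
  })

  qc <- run_stage("qc", {
    fr <- filter_variants(sim$calls, cfg$depth_min, cfg$depth_max,
                          cfg$qual_min, mito_contig = NULL)
    fr2 <- exclude_het_without_ref_allele(fr$pass_set, sim$bundle$reference)
    merged <- new_filter_report(
      pass_set = fr2$pass_set, n_input = fr$n_input,
      n_fail_depth = fr$n_fail_depth, n_fail_quality = fr$n_fail_quality,
      n_fail_het_no_ref = fr2$n_fail_het_no_ref,
      thresholds = fr$thresholds
    )
    conc <- array_concordance(
      select(filter(sim$calls, .data$vtype == "snp"),
             "contig", "pos", "genotype"),
      sim$array_gt
    )
    ctg <- names(sim$bundle$reference)[1]
    cov <- coverage_profile(sim$depths[[ctg]], sim$bundle$reference[[ctg]],
                            window = cfg$window)
    readr::write_tsv(tidy(merged), file.path(cfg$out_dir, "filter_report.tsv"))
    readr::write_tsv(cov$windows, file.path(cfg$out_dir, "coverage_windows.tsv"))
    list(filter = merged, concordance = conc, coverage = cov)
  })

  ann <- run_stage("annotate", {
    annotated <- annotate_variants(qc$filter$pass_set, sim$bundle,
                                   upstream_window = cfg$upstream_window)
    prof <- tss_profile(annotated, sim$bundle$transcripts,
                        half_window = cfg$tss_half_window, bin = cfg$tss_bin)
    readr::write_tsv(annotated, file.path(cfg$out_dir, "annotated.tsv"))
    readr::write_tsv(prof, file.path(cfg$out_dir, "tss_profile.tsv"))
    list(annotated = annotated, tss = prof)
  })

  cmp <- run_stage("compare", {
    subject <- filter(qc$filter$pass_set, .data$vtype == "snp")
    shared <- purrr::map_dbl(sim$catalogs, function(cat) {
      shared_fraction(subject, cat)$pct
    })
    nov <- novel_variants(subject, catalogs = sim$catalogs)
    part <- partition_novel(nov$novel, sim$bundle$transcripts,
                            sim$bundle$repeats)
    readr::write_tsv(part$counts, file.path(cfg$out_dir, "novel_partition.tsv"))
    list(shared_pct = shared, novel = nov, partition = part)
  })

  risk <- run_stage("risk", {
    assessments <- lapply(sim$risk$prevalence$disease, function(d) {
      assess_risk(sim$risk, d, r2_max = cfg$r2_max)
    })
    names(assessments) <- sim$risk$prevalence$disease
    glances <- bind_rows(lapply(assessments, glance))
    readr::write_tsv(glances, file.path(cfg$out_dir, "risk_summary.tsv"))
    readr::write_tsv(tidy(assessments[[1]]),
                     file.path(cfg$out_dir, "riskogram.tsv"))
    pgx <- pgx_lookup(sim$risk$subject_genotypes, sim$risk$pgx)
    readr::write_tsv(pgx, file.path(cfg$out_dir, "pgx_matches.tsv"))
    list(assessments = assessments, pgx = pgx)
  })

  mt <- run_stage("mtdna", {
    vars <- mt_variants(sim$mt_subject$sequence, sim$bundle$mt_reference)
    cls <- mt_classify(vars, sim$bundle$mt_regions, sim$bundle$mt_reference)
    readr::write_tsv(cls$per_variant, file.path(cfg$out_dir, "mt_variants.tsv"))
    list(variants = vars, classification = cls)
  })

  summ <- run_stage("summary", {
    s <- summary_table(qc$filter, qc$coverage, cmp$novel,
                       concordance = qc$concordance)
    readr::write_tsv(s, file.path(cfg$out_dir, "summary.tsv"))
    s
  })

  jsonlite::write_json(
    cfg[order(names(cfg))], file.path(cfg$out_dir, "config.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(config = cfg, sim = sim, qc = qc, annotation = ann,
                 comparison = cmp, risk = risk, mtdna = mt, summary = summ))
}
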