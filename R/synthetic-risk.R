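# Synthetic disease-risk inputs: an association database with
# genotype-specific likelihood ratios derived from simulated case/control
# genotype frequencies, an LD table, prevalence strata, a reference
# population genotype panel, subject genotypes and a pharmacogenomics table.

PGX_DRUGS <- c("metformin", "warfarin", "simvastatin", "interferon-beta",
               "fluorouracil", "ribavirin", "amitriptyline", "bucindolol")
PGX_GENES <- c("ATM", "CYP2C9", "VKORC1", "SLCO1B1", "GPC5", "DPYD",
               "ITPA", "ABCB1")
DISEASE_NAMES <- c("multiple_sclerosis", "uterine_leiomyoma", "asthma",
                   "obesity", "type2_diabetes", "hypertension",
                   "coronary_artery_disease", "macular_degeneration")

# Hardy-Weinberg genotype frequencies for risk-allele frequency p, keyed by
# genotype strings built from (ref, alt) alleles. The risk allele is `alt`.
hw_freqs <- function(p, ref, alt) {
  g <- c(paste(sort(c(ref, ref)), collapse = "/"),
         paste(sort(c(ref, alt)), collapse = "/"),
         paste(sort(c(alt, alt)), collapse = "/"))
  setNames(c((1 - p)^2, 2 * p * (1 - p), p^2), g)
}

#' Generate a synthetic disease-risk bundle
#'
#' Builds the inputs of a likelihood-ratio risk assessment. For each disease
#' a set of SNPs is simulated under a per-allele odds model: the control
#' population carries the risk allele at frequency `p`, cases at the
#' frequency implied by multiplying the allele odds by an effect size drawn
#' around 1. Genotype frequencies follow Hardy-Weinberg within each group
#' and the likelihood ratio of genotype `g` is the case frequency of `g`
#' divided by its control frequency; a zero control frequency with non-zero
#' case frequency is capped at `lr_cap` and flagged. The bundle also carries
#' a symmetric LD table (a fraction of within-disease pairs above the usual
#' 0.3 pruning threshold), one prevalence stratum per disease, a genotype
#' panel of `panel_size` individuals drawn from control frequencies
#' (mirroring a 101-individual reference-population comparison), subject
#' genotypes, and a pharmacogenomics lookup table. The full generative model
#' is stored in `manifest` for oracle recomputation.
#'
#' @param n_diseases Number of diseases.
#' @param snps_per_disease Associated SNPs per disease.
#' @param panel_size Reference-population panel size.
#' @param n_pgx Rows in the pharmacogenomics table.
#' @param ld_conflict_prob Probability that a within-disease SNP pair is in
#'   LD above 0.3.
#' @param lr_cap Cap for likelihood ratios with a zero denominator.
#' @param seed Integer seed.
#' @return A `risk_bundle` list: `associations`, `ld`, `prevalence`,
#'   `panel`, `subject_genotypes`, `pgx`, `manifest`.
#' @export
generate_risk_bundle <- function(n_diseases = 5,
                                 snps_per_disease = 8,
                                 panel_size = 101,
                                 n_pgx = 10,
                                 ld_conflict_prob = 0.25,
                                 lr_cap = 1000,
                                 seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n_diseases < 1 || snps_per_disease < 1 || panel_size < 1) {
    abort("counts must be positive")
  }
  assert_fraction(ld_conflict_prob, "ld_conflict_prob")

  with_seed(seed, {
    diseases <- DISEASE_NAMES[
      ((seq_len(n_diseases) - 1L) %% length(DISEASE_NAMES)) + 1L]
    diseases <- make.unique(diseases, sep = "_")

    snp_id <- 0L
    model_rows <- list()
    assoc_rows <- list()
    ld_rows <- list()
    for (d in diseases) {
      rsids <- character(snps_per_disease)
      for (k in seq_len(snps_per_disease)) {
        snp_id <- snp_id + 1L
        rsid <- sprintf("rs%06d", snp_id)
        rsids[k] <- rsid
        al <- sample(c("A", "C", "G", "T"), 2)
        p_ctrl <- runif(1, 0.1, 0.9)
        or_allele <- exp(stats::rnorm(1, 0, 0.35))
        odds_case <- p_ctrl / (1 - p_ctrl) * or_allele
        p_case <- odds_case / (1 + odds_case)
        f_ctrl <- hw_freqs(p_ctrl, al[1], al[2])
        f_case <- hw_freqs(p_case, al[1], al[2])
        lr <- f_case / f_ctrl
        capped <- !is.finite(lr) & f_case > 0
        lr[capped] <- lr_cap
        lr[f_case == 0 & f_ctrl == 0] <- 1
        n_studies <- sample(1:12, 1)
        n_samples <- sample(500:50000, 1)
        model_rows[[snp_id]] <- tibble(
          disease = d, rsid = rsid, genotype = names(f_ctrl),
          freq_case = unname(f_case), freq_control = unname(f_ctrl)
        )
        assoc_rows[[snp_id]] <- tibble(
          rsid = rsid, contig = "chr1", pos = 1000000L + snp_id * 1000L,
          disease = d, genotype = names(f_ctrl), lr = unname(lr),
          lr_capped = unname(capped),
          n_studies = n_studies, n_samples = n_samples
        )
      }
      pairs <- utils::combn(rsids, 2)
      conflict <- runif(ncol(pairs)) < ld_conflict_prob
      ld_rows[[d]] <- tibble(
        rsid_a = pairs[1, ], rsid_b = pairs[2, ],
        r2 = ifelse(conflict, runif(ncol(pairs), 0.31, 0.9),
                    runif(ncol(pairs), 0, 0.3))
      )
    }
    associations <- bind_rows(assoc_rows)
    model <- bind_rows(model_rows)
    ld <- bind_rows(ld_rows)

    prevalence <- tibble(
      disease = diseases,
      age_lo = 40L, age_hi = 60L, sex = "F", ethnicity = "SA",
      pretest_prob = round(runif(n_diseases, 0.01, 0.25), 4)
    )

    # panel + subject genotypes sampled from control frequencies
    geno_tbl <- distinct(model, .data$rsid, .data$genotype,
                         .data$freq_control)
    sample_genotypes <- function() {
      geno_tbl %>%
        group_by(.data$rsid) %>%
        summarise(genotype = sample(.data$genotype, 1,
                                    prob = .data$freq_control),
                  .groups = "drop")
    }
    panel <- purrr::map_dfr(seq_len(panel_size), function(i) {
      mutate(sample_genotypes(), individual = sprintf("P%03d", i))
    }) %>% select("individual", "rsid", "genotype")
    subject <- sample_genotypes()

    pgx <- tibble(
      rsid = sprintf("rs9%05d", seq_len(n_pgx)),
      gene = sample(PGX_GENES, n_pgx, replace = TRUE),
      genotype = purrr::map_chr(seq_len(n_pgx), function(i) {
        paste(sort(sample(c("A", "C", "G", "T"), 2, replace = TRUE)),
              collapse = "/")
      }),
      drug = sample(PGX_DRUGS, n_pgx, replace = TRUE),
      outcome_text = sprintf("altered response to %s (synthetic record %d)",
                             sample(PGX_DRUGS, n_pgx, replace = TRUE),
                             seq_len(n_pgx))
    )
    # subject carries the tabulated genotype at about half the PGx loci
    pgx_subject <- tibble(
      rsid = pgx$rsid,
      genotype = ifelse(
        runif(n_pgx) < 0.5, pgx$genotype,
        vapply(pgx$genotype, perturb_genotype, character(1))
      )
    )
    subject <- bind_rows(subject, pgx_subject)

    structure(
      list(
        associations = associations,
        ld = ld,
        prevalence = prevalence,
        panel = panel,
        subject_genotypes = subject,
        pgx = pgx,
        manifest = list(
          seed = seed,
          n_diseases = n_diseases,
          snps_per_disease = snps_per_disease,
          panel_size = panel_size,
          lr_cap = lr_cap,
          model = model,
          prevalence = prevalence
        )
      ),
      class = "risk_bundle"
    )
  })
}

#' Simulate a case/control cohort from a risk bundle's generative model
#'
#' Draws `n` individuals for one disease: case status from the stratum's
#' pre-test probability, then a genotype at every associated SNP from the
#' case or control genotype frequencies stored in the bundle manifest.
#' SNP genotypes are conditionally independent given case status, which is
#' exactly the assumption under which multiplying per-SNP likelihood ratios
#' is valid, so the cohort is the natural testbed for calibration of the
#' post-test probabilities.
#'
#' @param bundle A `risk_bundle`.
#' @param disease Disease name present in the bundle.
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return List with `status` (tibble individual, case) and `genotypes`
#'   (tibble individual, rsid, genotype).
#' @export
simulate_risk_cohort <- function(bundle, disease, n = 2000, seed) {
  if (missing(seed)) abort("`seed` is required")
  model <- filter(bundle$manifest$model, .data$disease == !!disease)
  if (nrow(model) == 0) abort(sprintf("unknown disease: %s", disease))
  p0 <- bundle$prevalence$pretest_prob[bundle$prevalence$disease == disease]

  with_seed(seed, {
    case <- runif(n) < p0
    ids <- sprintf("I%05d", seq_len(n))
    genos <- purrr::map_dfr(split(model, model$rsid), function(m) {
      g <- character(n)
      if (any(case)) {
        g[case] <- sample(m$genotype, sum(case), replace = TRUE,
                          prob = m$freq_case)
      }
      if (any(!case)) {
        g[!case] <- sample(m$genotype, sum(!case), replace = TRUE,
                           prob = m$freq_control)
      }
      tibble(individual = ids, rsid = m$rsid[1], genotype = g)
    })
    list(
      status = tibble(individual = sprintf("I%05d", seq_len(n)), case = case),
      genotypes = genos
    )
  })
}
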