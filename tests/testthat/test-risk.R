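# Likelihood-ratio risk engine.

mk_assoc <- function(rsid, lr_map, n_studies = 5, n_samples = 1000,
                     disease = "d") {
  tibble::tibble(
    rsid = rsid, contig = "chr1", pos = 1L, disease = disease,
    genotype = names(lr_map), lr = unname(lr_map),
    n_studies = n_studies, n_samples = n_samples
  )
}

test_that("pre-test lookup requires exactly one matching stratum", {
  tbl <- tibble::tibble(
    disease = c("asthma", "asthma"), age_lo = c(40L, 20L),
    age_hi = c(60L, 39L), sex = "F", ethnicity = "SA",
    pretest_prob = c(0.10, 0.05)
  )
  expect_equal(pretest_probability(tbl, "asthma", 50, "F", "SA"), 0.10)
  expect_error(pretest_probability(tbl, "asthma", 70, "F", "SA"),
               "available")
  dup <- dplyr::bind_rows(tbl[1, ], tbl[1, ])
  expect_error(pretest_probability(dup, "asthma", 50, "F", "SA"),
               "ambiguous")
})

test_that("LD pruning keeps the strongest record of each conflicting pair", {
  recs <- dplyr::bind_rows(
    mk_assoc("rs1", c(`A/A` = 1.2), n_studies = 5),
    mk_assoc("rs2", c(`A/A` = 1.5), n_studies = 2)
  )
  ld <- tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.5)
  kept <- ld_prune(recs, ld)
  expect_equal(unique(kept$rsid), "rs1")
  # below threshold: both kept
  ld2 <- tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.2)
  expect_setequal(unique(ld_prune(recs, ld2)$rsid), c("rs1", "rs2"))
  # no LD rows at all
  expect_setequal(unique(ld_prune(recs, ld2[0, ])$rsid), c("rs1", "rs2"))
})

test_that("greedy pruning matches exhaustive enumeration on random instances", {
  for (seed in 1:5) {
    inst <- withr::with_seed(seed, {
      m <- 8
      info <- tibble::tibble(
        rsid = sprintf("rs%02d", 1:m),
        n_studies = sample(1:6, m, replace = TRUE),
        n_samples = sample(100:999, m)
      )
      pairs <- t(combn(info$rsid, 2))
      ld <- tibble::tibble(
        rsid_a = pairs[, 1], rsid_b = pairs[, 2],
        r2 = ifelse(runif(nrow(pairs)) < 0.3, runif(nrow(pairs), 0.31, 1),
                    runif(nrow(pairs), 0, 0.3))
      )
      list(info = info, ld = ld)
    })
    recs <- dplyr::bind_rows(lapply(seq_len(nrow(inst$info)), function(i) {
      mk_assoc(inst$info$rsid[i], c(`A/A` = 1),
               n_studies = inst$info$n_studies[i],
               n_samples = inst$info$n_samples[i])
    }))
    kept <- unique(ld_prune(recs, inst$ld)$rsid)
    lookup <- function(a, b) {
      hit <- inst$ld$r2[(inst$ld$rsid_a == a & inst$ld$rsid_b %in% b) |
                          (inst$ld$rsid_b == a & inst$ld$rsid_a %in% b)]
      if (length(hit) == 0) 0 else max(hit)
    }
    want <- oracle_ld_prune(inst$info, lookup, 0.3)
    expect_setequal(kept, want)
    # no kept pair exceeds the threshold
    if (length(kept) > 1) {
      for (a in kept) for (b in setdiff(kept, a)) {
        expect_lte(lookup(a, b), 0.3)
      }
    }
  }
})

test_that("combined LR multiplies genotype LRs with factor 1 for missing", {
  kept <- dplyr::bind_rows(
    mk_assoc("rs1", c(`A/A` = 2.0, `A/G` = 1.0)),
    mk_assoc("rs2", c(`A/A` = 0.5))
  )
  gts <- tibble::tibble(rsid = c("rs1", "rs2"), genotype = c("A/A", "A/A"))
  expect_equal(combined_lr(gts, kept)$lambda, 1.0) # 2.0 * 0.5
  # all LRs 1
  ones <- dplyr::bind_rows(mk_assoc("rs1", c(`A/A` = 1)),
                           mk_assoc("rs2", c(`A/A` = 1)))
  expect_equal(combined_lr(gts, ones)$lambda, 1.0)
  # missing genotype contributes 1 and is counted
  gts2 <- tibble::tibble(rsid = "rs1", genotype = "A/A")
  res <- suppressMessages(combined_lr(gts2, kept))
  expect_equal(res$lambda, 2.0)
  expect_equal(res$n_uninformative, 1)
  # unordered genotype comparison
  gts3 <- tibble::tibble(rsid = c("rs1", "rs2"), genotype = c("G/A", "A/A"))
  expect_equal(combined_lr(gts3, kept)$lambda, 0.5)
  bad <- mk_assoc("rs1", c(`A/A` = 0))
  expect_error(combined_lr(gts, bad), "positive")
})

test_that("post-test probability is Bayes on the odds scale", {
  expect_equal(posttest_probability(0.3, 1), 0.3) # identity at LR 1
  expect_equal(posttest_probability(0.5, 3), 0.75)
  expect_error(posttest_probability(1.2, 1), "0, 1")
  expect_error(posttest_probability(0.5, -1), "> 0")
  # strict monotonicity in both arguments
  expect_gt(posttest_probability(0.3, 2), posttest_probability(0.3, 1.9))
  expect_gt(posttest_probability(0.31, 2), posttest_probability(0.3, 2))
  # odds-form consistency to machine precision
  p0 <- 0.137; lam <- 4.21
  p1 <- posttest_probability(p0, lam)
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), lam, tolerance = 1e-12)
})

test_that("single-SNP post-test equals the Bayes posterior of the joint", {
  # generative model: prevalence p0, genotype freqs by case status
  p0 <- 0.08
  f_case <- c(`A/A` = 0.5, `A/G` = 0.4, `G/G` = 0.1)
  f_ctrl <- c(`A/A` = 0.25, `A/G` = 0.5, `G/G` = 0.25)
  for (g in names(f_case)) {
    lr <- f_case[[g]] / f_ctrl[[g]]
    p1 <- posttest_probability(p0, lr)
    bayes <- p0 * f_case[[g]] / (p0 * f_case[[g]] + (1 - p0) * f_ctrl[[g]])
    expect_equal(p1, bayes, tolerance = 1e-12)
  }
})

test_that("two conditionally independent SNPs multiply to the joint LR", {
  f1c <- c(`A/A` = 0.6, `A/G` = 0.4); f1n <- c(`A/A` = 0.3, `A/G` = 0.7)
  f2c <- c(`C/C` = 0.2, `C/T` = 0.8); f2n <- c(`C/C` = 0.5, `C/T` = 0.5)
  kept <- dplyr::bind_rows(
    mk_assoc("rs1", f1c / f1n),
    mk_assoc("rs2", f2c / f2n)
  )
  for (g1 in names(f1c)) for (g2 in names(f2c)) {
    gts <- tibble::tibble(rsid = c("rs1", "rs2"), genotype = c(g1, g2))
    lambda <- combined_lr(gts, kept)$lambda
    joint <- (f1c[[g1]] * f2c[[g2]]) / (f1n[[g1]] * f2n[[g2]])
    expect_equal(lambda, joint, tolerance = 1e-12)
  }
})

test_that("panel percentile uses a strict-inequality count", {
  kept <- mk_assoc("rs1", c(`A/A` = 2.0, `G/G` = 0.5))
  panel <- tibble::tibble(
    individual = sprintf("P%d", 1:4),
    rsid = "rs1",
    genotype = c("G/G", "G/G", "A/A", "G/G")
  )
  res <- risk_percentile(2.0, panel, kept)
  expect_equal(res$percentile, 75) # three of four strictly below
  # all ties: strict convention gives 0
  res2 <- risk_percentile(0.5, panel[panel$genotype == "G/G", ], kept)
  expect_equal(res2$percentile, 0)
  expect_error(risk_percentile(1, panel[0, ], kept), "empty")
  # direct count oracle on a random panel
  b <- generate_risk_bundle(n_diseases = 1, snps_per_disease = 5,
                            panel_size = 101, seed = 91)
  d <- b$prevalence$disease[1]
  recs <- dplyr::filter(b$associations, disease == d)
  keptb <- ld_prune(recs, b$ld)
  lam <- combined_lr(b$subject_genotypes, keptb)$lambda
  res3 <- risk_percentile(lam, b$panel, keptb)
  below <- sum(vapply(split(b$panel, b$panel$individual), function(g) {
    combined_lr(g, keptb)$lambda
  }, numeric(1)) < lam)
  expect_equal(res3$percentile, 100 * below / 101)
})

test_that("riskogram orders by evidence and ends at the combined post-test", {
  p0 <- 0.5
  kept <- dplyr::bind_rows(
    mk_assoc("rs1", c(`A/A` = 2.0), n_studies = 3),
    mk_assoc("rs2", c(`A/A` = 1.5), n_studies = 9)
  )
  gts <- tibble::tibble(rsid = c("rs1", "rs2"), genotype = "A/A")
  rog <- riskogram(p0, gts, kept)
  expect_equal(rog$rsid, c("rs2", "rs1")) # more studies first
  expect_equal(rog$cumulative_posttest[1], posttest_probability(0.5, 1.5))
  expect_equal(rog$cumulative_posttest[2],
               posttest_probability(p0, combined_lr(gts, kept)$lambda))
  # a single record with LR 2 from p0 = 0.5: odds 1 -> 2
  one <- riskogram(0.5, gts[1, ], kept[kept$rsid == "rs1", ])
  expect_equal(one$cumulative_posttest, 2 / 3)
  # empty kept set: empty series, summary probability is p0
  zero <- riskogram(p0, gts, kept[0, ])
  expect_equal(nrow(zero), 0)
  expect_equal(posttest_probability(p0, 1), p0)
})

test_that("doubling any single kept LR strictly increases the post-test", {
  b <- generate_risk_bundle(n_diseases = 1, snps_per_disease = 4, seed = 93)
  d <- b$prevalence$disease[1]
  kept <- ld_prune(dplyr::filter(b$associations, disease == d), b$ld)
  p0 <- b$prevalence$pretest_prob[1]
  base <- posttest_probability(
    p0, combined_lr(b$subject_genotypes, kept)$lambda)
  for (r in unique(kept$rsid)) {
    boosted <- dplyr::mutate(
      kept, lr = ifelse(rsid == r, lr * 2, lr))
    p1 <- posttest_probability(
      p0, combined_lr(b$subject_genotypes, boosted)$lambda)
    expect_gt(p1, base)
  }
})

test_that("pgx lookup is an exact unordered-genotype join", {
  tbl <- tibble::tibble(
    rsid = c("rs4585", "rs4585", "rs111"),
    gene = c("ATM", "ATM", "X"),
    genotype = c("G/G", "A/G", "T/T"),
    drug = c("metformin", "metformin", "other"),
    outcome_text = c("better response", "typical response", "n/a")
  )
  gts <- tibble::tibble(rsid = "rs4585", genotype = "G/G")
  hit <- pgx_lookup(gts, tbl)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$outcome_text, "better response")
  # unordered match
  expect_equal(nrow(pgx_lookup(tibble::tibble(rsid = "rs4585",
                                              genotype = "G/G"), tbl)), 1)
  # absent genotype: empty result
  expect_equal(nrow(pgx_lookup(tibble::tibble(rsid = "rs4585",
                                              genotype = "A/A"), tbl)), 0)
  # random genotypes vs table equals a nested-loop join
  b <- generate_risk_bundle(n_pgx = 30, seed = 95)
  got <- pgx_lookup(b$subject_genotypes, b$pgx)
  subj <- b$subject_genotypes
  want <- 0
  for (i in seq_len(nrow(b$pgx))) {
    for (j in seq_len(nrow(subj))) {
      if (b$pgx$rsid[i] == subj$rsid[j] &&
          normalise_genotype(b$pgx$genotype[i]) ==
            normalise_genotype(subj$genotype[j])) {
        want <- want + 1
      }
    }
  }
  expect_equal(nrow(got), want)
})

test_that("assess_risk ties the pieces together consistently", {
  b <- generate_risk_bundle(seed = 97)
  d <- b$prevalence$disease[2]
  ra <- assess_risk(b, d)
  expect_s3_class(ra, "risk_assessment")
  expect_equal(ra$posttest,
               posttest_probability(ra$pretest, ra$combined_lr))
  expect_equal(dplyr::last(ra$riskogram$cumulative_posttest), ra$posttest)
  # kept records never contain a pair above the threshold
  keptr <- unique(ra$kept$rsid)
  if (length(keptr) > 1) {
    for (a in keptr) for (bb in setdiff(keptr, a)) {
      r2 <- b$ld$r2[(b$ld$rsid_a == a & b$ld$rsid_b == bb) |
                      (b$ld$rsid_b == a & b$ld$rsid_a == bb)]
      if (length(r2) > 0) expect_lte(max(r2), 0.3)
    }
  }
  g <- glance(ra)
  expect_equal(g$posttest, ra$posttest)
  expect_equal(nrow(tidy(ra)), dplyr::n_distinct(ra$kept$rsid))
})
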