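---
title: "Interpreting a personal genome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting a personal genome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgint)
library(dplyr)
```

`pgint` re-implements, as a reusable and fully tested pipeline, the analysis
stages used to interpret a single deeply sequenced human genome: variant
quality control, functional and regulatory annotation, cross-genome
comparison, mitochondrial variant classification, and a Bayesian
likelihood-ratio assessment of disease risk. Genome-scale inputs (billions of
aligned bases, millions of variants) are not needed to validate the methods;
instead the package ships a synthetic-data module that generates every input
with planted, manifest-recorded ground truth, so each stage can be checked
against exact expectations.

## Variant quality control

Variant calls carry a genotype, a read depth `d` and a phred-scaled quality
`Q`. The filters are conjunctive:

* depth: `5 <= d <= 60` (both bounds inclusive). The lower bound guards
  against undersampled genotypes, the upper against collapsed repeats and
  mapping artifacts. The depth rule is waived on the mitochondrial contig,
  whose copy number puts its coverage orders of magnitude above the nuclear
  genome; the quality rule still applies there. The source analyses are
  ambiguous about whether only the upper bound is exempt; `pgint` waives
  both bounds on the mito contig, which is flagged here as a design choice
  rather than asserted intent.
* quality: `Q >= 30`, i.e. an error probability of at most 1e-3.
* heterozygous calls whose two alleles both differ from the reference base
  are removed; such calls are usually alignment artifacts. Homozygous
  non-reference calls are untouched by this rule.

A call failing several rules is attributed to the first failing rule in the
order depth, quality, het-no-ref. This makes the report counts additive
(`n_input = n_pass + sum(fails)`) and therefore testable; because the rules
are conjunctive, the retained set is identical under any application order,
and a property test asserts exactly that.

Array concordance compares genotypes as unordered allele pairs over the
intersection of sites; missing genotypes are excluded from the denominator,
and an empty intersection is an error rather than 0%. Percentages are
rounded half-up at one decimal, the precision at which such concordances are
conventionally quoted (base R's `round()` is banker's rounding, which would
turn 98.65 into 98.6).

## Coverage model

Sequencing depth per base is summarised as a histogram over non-N reference
bases, with a Poisson of matched mean drawn alongside. Real libraries are
overdispersed — the observed distribution carries more weight in both tails
than a Poisson — so the synthetic depth model is gamma-Poisson (negative
binomial): mean `mu`, variance `mu + phi * mu^2`, with `phi` a configuration
knob defaulting to 0.15 and `phi = 0` degenerating to Poisson. GC bias is
summarised in non-overlapping 50-kb windows (GC fraction vs mean depth); the
final partial window of a contig is emitted with its true length and
flagged, so that window-level GC counts exactly conserve the genome total — a
conservation invariant the tests assert.

## Region and consequence annotation

Transcripts are feature-long tables (exon, CDS, UTR rows). Internally all
intervals are 1-based closed, the convention of the R interval stack
(IRanges); BED input/output is 0-based half-open and converted exactly once,
in the readers and writers. Each variant receives exactly one region label
under the severity order

`coding_exon > utr5 > utr3 > noncoding_exon > intron > intergenic`

across all overlapping transcripts; ties between transcripts at equal
severity go to the lexicographically first transcript id, and the identity
of the transcript used is returned so consequence calling can reuse it.
Deletions are tested by the reference span they consume, insertions by their
single anchor base — a convention choice where upstream formats are silent.
Variants are counted independently in the gene and repeat trees: a variant
in both a LINE and a gene contributes to both tallies.

Coding consequences are computed on the spliced CDS in translation order
(reverse-complemented for minus-strand transcripts): a substitution is
synonymous, missense, or nonsense (alternate codon is a stop) under the
standard nuclear code; an indel whose net in-CDS length change is divisible
by 3 is in-frame, otherwise a frameshift, in which case the mutated CDS is
translated from the start and the index of the first stop codon is reported.
Indels spanning a CDS boundary are flagged and their frame computed from the
in-CDS bases only. Two properties pin the implementation down: effects are
invariant under reverse-complementing the entire genome, and
synonymous + missense + nonsense always equals the number of coding-exon
SNPs.

TSS metaprofiles count variants in 50-bp bins across ±2 kb around each
transcription start site, in transcript orientation (minus-strand
transcripts mirrored), normalised per transcript. The window and bin are
configurable; the defaults resolve features on the ~50-bp scale reported
near promoters. TFBS overlap is only counted when the variant also lies in
some gene's 5-kb upstream window; enhancer overlap is genome-wide.

Gene-set enrichment is a one-sided hypergeometric test with
Benjamini–Hochberg correction and an FDR threshold of 0.05. This is a
deliberate, documented divergence from DAVID-style EASE scores (a penalised
hypergeometric): the plain tail probability has an exact independent oracle
(direct pmf summation) and no tuning constants.

## Cross-genome comparison

Sharing between variant catalogs is allele-aware by default: two genomes
share a site when they carry the same position *and* at least one common
alternate allele. Position-only sharing is available behind a flag because
published comparisons mix both conventions; neither is asserted as the
original rule. Indels are left-normalised (shared trailing then leading
bases trimmed, position adjusted) before keying, since representation
differences otherwise inflate novelty. Novel variants are those present in
no panel and no catalog; they are partitioned into gene-only, repeat-only,
both, and other — four mutually exclusive labels whose counts must sum to
the novel total.

## Likelihood-ratio disease risk

For a disease with pre-test probability $p_0$ and genotype likelihood
ratios $LR_i = P(g_i \mid D) / P(g_i \mid \bar D)$ at SNPs independent
given disease status,

$$\mathrm{odds}(p_1) = \Lambda \cdot \mathrm{odds}(p_0), \qquad
  \Lambda = \prod_i LR_i .$$

The machinery and its assumptions:

* Pre-test probabilities come from a prevalence table stratified by
  disease, age range, sex and ethnicity; the lookup requires exactly one
  matching stratum and errors otherwise (listing what is available) — a
  silent fallback would silently change a risk estimate.
* Multiplying LRs is only valid across (conditionally) independent SNPs, so
  records in linkage disequilibrium with $r^2 > 0.3$ are pruned greedily:
  records ranked by strength of evidence — number of studies, then sample
  count, then rsid for determinism ("strongest evidence" is not defined in
  the source; this operationalisation is ours) — and accepted when their
  $r^2$ against every kept record is at or below the threshold. Pruning is
  per disease. The greedy result equals the lexicographically first maximal
  conflict-free subset in priority order, which the tests verify against
  exhaustive enumeration.
* A missing subject (or panel) genotype at a kept SNP contributes a factor
  of 1 — no information — and is logged, never imputed.
* LRs are accumulated in log space for numerical stability; the contract is
  the plain product, and an odds-form identity
  $\mathrm{odds}(p_1)/\mathrm{odds}(p_0) = \Lambda$ is asserted to machine
  precision.
* The population percentile recomputes $\Lambda$ for every panel individual
  over the same kept records and counts strictly smaller values; ties do
  not count toward the percentile. With a shared $p_0$, comparing $\Lambda$
  is equivalent to comparing post-test probabilities, so the probability
  scale needs no separate convention.
* The RiskOgram orders kept SNPs by decreasing number of supporting
  studies and reports the post-test probability after each successive LR;
  its last entry equals the full post-test probability by construction.

Calibration is checked on a generative cohort: 2,000 individuals drawn from
the bundle's true case/control genotype frequencies (independent given case
status — exactly the assumption under which LR multiplication is valid),
binned into $\Lambda$ deciles. The mean absolute gap between the mean
predicted post-test probability and the empirical case fraction across
deciles must stay under 3 percentage points; the mean-absolute form was
chosen because per-decile binomial noise at this cohort size is itself
about 1.5–3 points, which a max-over-deciles criterion would conflate with
miscalibration.

```{r risk-example}
rb <- generate_risk_bundle(n_diseases = 2, snps_per_disease = 6, seed = 7)
ra <- assess_risk(rb, rb$prevalence$disease[1])
glance(ra)
```

## Mitochondrial variants

The subject and reference mitochondrial sequences are compared
coordinate-wise (equal length required; indel alignment is out of scope).
Each substitution is assigned to a region — control, non-coding, RNA gene,
or protein-coding — with origin-wrapping regions represented as wrapped
intervals and handled on the unrolled circle; a position covered by several
regions takes the first covering region in table order (region semantics
live in the caller-supplied region table). Protein-coding substitutions are
translated with the vertebrate mitochondrial genetic code (TGA = Trp,
AGA/AGG = stop), a choice the source does not state but which is the
standard for human mtDNA. Classification is invariant under rotating the
circular origin, which the tests assert.

## The synthetic-data module

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated under:

* one 100-kb contig with 5 genes (2–4 exons, planted open reading frames
  written into the sequence so consequence calling operates on real
  codons), a repeat track weighted LINE/L1 41%, SINE/Alu 30%, and
  TFBS/enhancer features placed relative to 5-kb upstream windows;
* variant calls with a 5.6% exonic fraction for SNPs (4.1% for indels),
  60.3% heterozygosity, gamma-Poisson depth of mean 34.94 and
  overdispersion 0.15, and planted failure fractions for each filter rule;
* a 1.3% array discordance rate;
* an association database whose LRs are case/control genotype-frequency
  ratios under a per-allele odds model with Hardy–Weinberg genotype
  frequencies in each group (the LR estimation details of the original
  database are not published; this frequency-ratio definition is the
  stand-in generative model, with zero-denominator LRs capped at 1000 —
  the cap keeps products finite without changing their ordering);
* a 101-individual reference genotype panel, mirroring the size of the
  population comparison the method is used for;
* a mitochondrial subject carrying 35 planted substitutions split
  9/1/5/20 across control/non-coding/RNA/protein regions with a 16/4
  synonymous/non-synonymous split.

Every generator draws from a single integer seed through a local RNG scope
(no global state is touched), regeneration is byte-identical on disk, and
every manifest count is recoverable by an independent brute-force scan of
the emitted files — both are tested.

What the generator does **not** emulate: read-level artifacts (mapping
error, duplicates, base-quality miscalibration), real linkage
disequilibrium (the LD table is metadata for the pruning step, not a
property of the sampled genotypes), realistic allele-frequency spectra, and
genome-scale counts. Passing tests therefore demonstrate that the
*methods* — interval arithmetic, codon translation, set accounting, Bayes
on the odds scale — are correct under controlled conditions; they do not
certify caller performance or population-genetic realism on real data.

## Numerical choices and test problem sizes

* Reported percentages round half-up at the printed precision (one decimal
  for concordance and novelty, two for mean depth and partition shares).
* Exact-recovery checks (planted exonic counts, novel fractions, mtDNA
  truth) use equality, since planting is by construction; stochastic
  recoveries (array discordance) use a four-standard-deviation binomial
  envelope plus the rounding step.
* Oracle-equivalence suites run at deliberately small sizes — hundreds to a
  few thousand variants, LD instances of eight records for exhaustive
  subset enumeration, 100-gene universes for the hypergeometric — sizes at
  which the brute-force oracles are exact and fast while still exercising
  every code path.
* The acceptance script measures at 5,000 SNPs / 500 indels and a
  2,000-individual calibration cohort, the package's chosen balance between
  sampling noise and runtime.

## Known limitations

* Region semantics for multi-transcript genes reduce to a single
  most-severe label; isoform-level reporting is retained only through the
  transcript id used.
* The enrichment test is a plain hypergeometric, not an EASE-penalised
  variant, so p-values differ from DAVID output by construction.
* Mitochondrial heteroplasmy, haplogroup assignment and phylogenetics are
  out of scope, as are read alignment, duplicate marking, de novo assembly
  and damage-prediction scores.
* Liftover between genome builds is not implemented; catalogs must share a
  coordinate system.
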