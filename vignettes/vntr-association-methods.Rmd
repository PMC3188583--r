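---
title: "Methods: VNTR allele-size association, LD, and haplotype scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VNTR allele-size association, LD, and haplotype scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrassoc)
```

## The problem

Mucin genes carry variable number tandem repeat (VNTR) domains whose length
varies widely between chromosomes. In Southern-blot assays an allele is a
restriction-fragment length, read on a 0.05 kb grid; in PCR assays it is an
integer repeat count. `vntrassoc` implements the statistical path from a
cohort of individuals — each with a binary severity phenotype (ascertained
from the extremes of a quantitative lung phenotype), two VNTR allele sizes
per locus, and flanking SNP genotypes — to four kinds of conclusions:

1. Does the allele-size distribution differ between severity groups
   (rank-sum on chromosomes), and does any *individual* allele size
   associate with severity (designated-allele exact tests with an explicit
   multiple-testing ledger)?
2. Can a bimodal spectrum be dichotomized into short (S) and long (L)
   alleles, and do S/L genotypes associate with severity?
3. How strong is linkage disequilibrium (LD) between VNTR size classes and
   flanking SNPs (two-locus EM, r², chi-square maps)?
4. Are two same-mode allele sizes (e.g. 6.3 kb and 6.4 kb) *genetically
   distinct*, i.e. do they carry different SNP backgrounds (nested
   allele-partition likelihood-ratio test), and do particular
   VNTR-class × SNP haplotypes drive the phenotype association
   (permutation haplotype score test)?

All user-facing functions take the cohort tibble first and return tibbles
(or small list-objects with `tidy()`/`glance()` methods), so analyses
compose with the pipe.

## Data model and conventions

Allele sizes are snapped to the locus grid on ingestion (strict mode
errors instead), canonicalized smaller-first, and all equality comparisons
go through integer grid keys, so 6.40 is never a floating-point near-miss
of 6.4. Genotypes are unordered; half-calls are rejected. Individuals
missing a locus are dropped *pairwise per analysis*, not globally — the
motivating study design types different subsets per gene, and per-analysis
n is always reported. Repeat-count loci use the same machinery with grid
unit 1.

## Designated-allele tests and the test ledger

For a designated allele D, each patient falls in one of three genotype
classes — (D,D), (D,non-D), (non-D,non-D) — and the 2×3 severity-by-class
table is tested with the Freeman–Halton generalization of Fisher's exact
test: the two-sided p value is the total hypergeometric probability of all
margin-consistent tables no more probable than the observed one
(probability ordering, relative tolerance 1e-7 on the comparison, matching
the convention of mainstream exact-test implementations). Enumeration is
exact over the full margin lattice; a size guard refuses hopeless tables
and points to the seeded Monte Carlo mode (`r2dtable` sampling with the
add-one estimator).

`designated_scan()` tests every allele whose frequency reaches 4%. The
threshold's basis is configurable: `"carriers"` (share of patients
carrying ≥ 1 copy; the default) or `"chromosomes"` (share of pooled
chromosomes). Carrier basis is the default because it is the reading under
which the published designated-allele table's full row set — including its
rarest row, which sits at 3.95% of chromosomes but 6.2% of carriers — is
reproducible from the printed counts.

Every test is registered in a `test_ledger()`. Families may be nested, and
a family's size may be *declared* when its full membership is known only
as a printed count (the published correction families of 8, 12, 15, 29 and
44 tests are of this kind); `bonferroni()` then reports
`min(1, p × family size)`.

The carrier odds ratio collapses the 2×3 table to carrier/non-carrier and
uses the Woolf log-SE interval, with the Haldane–Anscombe 0.5 correction
(flagged) when a cell is zero. The rank-sum comparison treats each
chromosome as one observation (as the source figures' chromosome counts
imply), with the tie-corrected normal approximation and no continuity
correction; the within-patient dependence of the two chromosomes is
acknowledged, not modeled, so its p values are mildly anti-conservative
for dependent chromosomes.

## Mixture-based short/long dichotomization

A two-component normal mixture is fit to the pooled spectrum by EM with
chromosome counts as weights (whether to weight by chromosomes or unique
sizes is a convention; chromosome weighting is ours). Initialization is a
deterministic weighted-median split — no random restarts, so fits are
reproducible — and the log-likelihood is asserted non-decreasing at every
iteration. Components are ordered by mean. Convergence is a log-likelihood
gain below 1e-8 or 500 iterations.

The published cut-point rule, "the average of two standard deviations from
the mean of the respective distributions", is ambiguous; we implement it
as the midpoint of (μ₁ + 2σ₁) and (μ₂ − 2σ₂), with the density-crossing
point as a configurable alternative and any fixed constant (e.g. a
biologically motivated 4.9 kb) as a bypass. The exact arithmetic behind
the study's 4.3 and 6.7 kb constants cannot be replicated without the raw
spectra, so those constants are treated as illustrative inputs, not
recoverable targets. Two safeguards gate dichotomization: a σ floor at the
0.01 kb grid scale (a collapsed component marks the fit degenerate) and a
BIC screen against a single normal (unimodal spectra are refused rather
than silently split). Both boundary conventions (S ≤ cut < L and
S < cut ≤ L) are explicit arguments because published analyses use both.

## Two-locus haplotype EM and LD

For a VNTR coded into k classes by an `allele_partition()` and a biallelic
SNP, haplotype frequencies are estimated by multinomial EM over unphased
genotype classes. Only double heterozygotes are phase-ambiguous; the
E-step splits them between their two resolutions in proportion to current
haplotype-frequency products. Convergence is a log-likelihood gain below
1e-10 or 1000 iterations, from a marginal-product start plus five jittered
restarts (kept only if one improves the log-likelihood by more than 1e-6;
the restart jitter uses fixed internal seeds so results are
deterministic). Zero frequencies are clamped at exactly 0. r² is computed
from the fitted 2×2 frequencies; the chi-square LD map tests SNP genotype
(0/1/2) against VNTR partition genotype (our convention; allele-level
tables are a defensible alternative and the choice is recorded in output
metadata), dropping and recording zero-margin rows/columns. Map p values
are binned at the conventional thresholds (0.1, 1e-5, 1e-10, 1e-50).

## The partition likelihood-ratio test

The differential-LD question — are 6.3 kb and 6.4 kb genetically distinct?
— is posed as a nested comparison of a fine partition (6.3 | 6.4 | other)
against a coarse one (6.3+6.4 | other) at each SNP. The two EMs run on the
same individuals, but their likelihoods live on different sample spaces,
so the coarse model is *lifted* to the fine space before comparison: under
the null, the SNP-conditional frequency is shared across a merged class
and the identity of the fine allele within its coarse class is an
independent, fully observed multinomial draw. The lifted null
log-likelihood factorizes exactly as `logL_coarse + logL_split`
(`logL_split` includes the pairing constant for within-class
heterozygotes), which guarantees `Λ = 2(logL_fine − logL_null) ≥ 0` and
gives the free-parameter difference

    df = (k_fine − k_coarse) × (SNP alleles − 1),

i.e. df = 1 for the 3-vs-2 comparison at a biallelic SNP: each extra fine
class contributes one extra SNP-conditional frequency, while its marginal
frequency is absorbed by the split term. A naive difference of raw
haplotype-simplex parameter counts would give 2; it double-counts the
split marginals, and with it the null rejection rate at α = 0.05 falls to
roughly 0.014 — the calibration suite (1000 null cohorts at study size)
confirms the df = 1 reference is the calibrated one. A true haplotype
frequency of zero puts the null on the simplex boundary; the chi-square
reference is used as in standard practice and the same calibration suite
quantifies the realized type-I error. Degenerate comparisons (fine equals
coarse on observed alleles) are refused. `scan_partitions()` applies
Bonferroni over the SNPs scanned and registers every test in the ledger.

## Haplotype score test

For haplotype–phenotype association, each individual's posterior expected
haplotype dosages are computed once under the phenotype-independent EM
model. With case indicator y and case fraction ȳ, the score vector is
U = Σᵢ (yᵢ − ȳ) dᵢ and its null covariance V = ȳ(1 − ȳ) Σᵢ (dᵢ − d̄)(dᵢ − d̄)ᵀ;
the global statistic is U V⁻ U (generalized inverse, rank recorded) and
per-haplotype z-scores use the diagonal. Significance comes from permuting
phenotype labels with dosages held fixed — the standard score-test
construction and the key approximation here (posteriors are *not*
re-estimated per permutation), which is what makes 100,000 permutations
(the default, matching the source protocol) tractable. Permutation p
values use the add-one estimator (b+1)/(B+1). Haplotypes below 0.5% EM
frequency are pooled into a rare class to stabilize the covariance
(configurable). Dosage coding is additive (the standard default; the
source protocol does not state its coding, and additive is recorded here
as ours). On phase-unambiguous cohorts the dosages are integral and the
global statistic reduces to a Pearson score statistic, which the test
suite exploits as a closed-form oracle
(`score_with_unambiguous_phase()`).

## The synthetic-cohort generator

No genotype data accompany the motivating study, so the generator defines
the study conditions under which everything is validated:

- **Spectrum.** The default allele-size spectrum is the pooled chromosome
  frequency implied by the published designated-allele genotype counts for
  the eight common alleles (6.25–6.50, 6.90, 7.00 kb), with the remaining
  5.8% of chromosomes collapsed into a 7.20 kb class. The study reports no
  direct spectrum table, so this reconstruction — bimodal around 6.30 and
  6.40 kb with sparse flanks, matching the drawn spectrum's shape — is the
  package's modeling choice.
- **Ascertainment.** Haplotypes pair at random (Hardy–Weinberg) in the
  population; mild individuals are drawn unconditionally and severe
  individuals by rejection with acceptance weight equal to the carrier
  odds ratio (default 2.5, the study's reported effect) for carriers of
  the designated allele (default 6.40 kb). This retrospective scheme
  mirrors extreme-phenotype case/control ascertainment, produces exactly
  the configured group sizes (defaults 194 severe / 274 mild), and makes
  the case-control carrier OR equal the configured value in expectation.
- **LD.** Each SNP allele is drawn Bernoulli with a probability
  conditional on the drawn VNTR allele, which creates allele-specific LD —
  including making two same-mode alleles distinguishable, the structure
  the partition LRT probes.

What the generator does **not** emulate: recombination and multi-SNP
haplotype structure beyond VNTR-conditional independence, covariates
(sex, ancestry), genotyping error, sizing noise off the 0.05 kb grid, and
any quantitative phenotype. Passing calibration therefore demonstrates
correctness of the statistics under the assumed generative structure, not
robustness to those real-data complications.

## Problem sizes and numerical choices

The validation suites run at the sizes a desk reproduction supports:
null calibration of the partition LRT uses 1000 simulated cohorts at the
study's 194/274 split (type-I error within 3 binomial SE of 0.05, KS
uniformity of null p values), its power arm 200 cohorts at a 0.9 vs 0.1
conditional contrast; OR recovery uses 200 cohorts (median within
[2.0, 3.1]); score-test calibration uses 500 null cohorts × 2000
permutations and a 200-cohort power arm. Exact-test oracles sweep 2×3
tables with totals ≤ 30 against brute-force enumeration and 2×2 tables
against the hypergeometric closed form; EM oracles compare against direct
simplex maximization on cohorts of ≤ 40 individuals (agreement within
1e-6 log-likelihood). Published in-table anchors (the four
designated-allele exact p values, the Bonferroni footnote arithmetic, the
carrier OR) are reproduced to two significant figures, the study's
reporting precision; package p values are always computed and compared
unrounded.

## Known limitations

- The rank-sum and exact tests treat chromosomes, or patients' genotype
  classes, as independent; neither models within-patient dependence or
  covariates. The study's covariate-adjusted SNP regressions are out of
  scope here.
- The partition LRT's chi-square reference is asymptotic and
  boundary-naive; trust the calibration suite's operating characteristics
  at your n, and re-run it at other sizes if they differ much from the
  defaults.
- The ledger reproduces declared family sizes without reconstructing
  every historical member test; corrected values are only as meaningful
  as the declared families.
- Mixture cut-points from spectra with heavy overlap are sensitive to the
  2σ rule's reading; both implemented readings are reported conventions,
  not estimands with standard errors.
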