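---
title: "Identifying prognostic SNPs in survival cohorts: models, tuning and design choices"
author: "coxsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying prognostic SNPs in survival cohorts: models, tuning and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The setting

A clinical cohort provides, for each of n patients, an observed time
t_i = min(T_i, C_i), an event indicator d_i = 1(T_i <= C_i), a small set of
r mandatory clinical covariates, and L SNP genotypes coded 0/1/2 as
risk-allele counts, with L often three orders of magnitude larger than n.
All modeling in `coxsnp` is based on the Cox proportional hazards model
with linear predictor x_i'beta and an unspecified baseline hazard; the
baseline is never estimated, and all inference runs through the Breslow
partial likelihood. The mandatory covariates are always part of the model
and never penalized: the question is which SNPs add prognostic information
beyond them.

Key assumptions inherited from this model: proportional hazards for every
fitted covariate, censoring non-informative given the covariates, and (for
the permutation test) censoring independent of the genotypes.

# Track 1: adjusted univariate screening

`screen_snps()` fits one Cox model per SNP. The default `joint` mode
re-estimates the mandatory covariates together with each SNP; the
`offset_fast` mode fits the mandatory model once and carries its linear
predictor as a fixed offset into L one-dimensional Newton fits, which is
what makes genome-wide screens of hundreds of thousands of SNPs take
seconds. The two modes solve slightly different problems — `offset_fast`
does not let the clinical coefficients adapt to each SNP — but with SNP
effects of realistic size the Wald p-values are nearly identical, and the
package's tests verify each mode against an independent survival
implementation of exactly the same model.

Multiplicity is handled by Benjamini–Hochberg FDR (`bh_fdr()`, delegating
to `p.adjust`): SNPs with adjusted values at or below the level (default
0.05) are selected. SNPs that cannot be tested — zero variance in the
cohort, collinear with a mandatory covariate, non-converged fits — receive
`NA` p-values and are excluded from the ranking, so the multiplicity m
counts only testable SNPs.

## Gene-region summaries by permutation min-P

Genes inherit evidence from their mapped SNPs through the min-P statistic:
the minimum univariate p-value over the M_k SNPs mapped to gene k. Its
null distribution cannot be read off a table because M_k varies and the
SNPs within a gene are in linkage disequilibrium, so `gene_minp_test()`
permutes the endpoint: the (time, status) pairs are jointly reassigned
against the unchanged covariate and genotype rows, all L p-values are
recomputed, and each gene's minimum is extracted. One permutation batch
serves all K genes simultaneously; running separate permutations per gene
would be statistically equivalent under this shared null but K times more
expensive. The permutation p-value is the proportion of the B permuted
minima at or below the observed one, so it is a multiple of 1/B and an
exact zero is possible — that is the resolution limit of B permutations,
reported as such. An optional `add_one` correction ((1 + count)/(1 + B))
is available but off by default. Gene-level multiplicity is reported both
as Bonferroni (the conservative genome-wide convention) and BH-FDR over
the K genes.

SNPs without a gene annotation simply do not participate at the gene
level; mappings are many-to-many, so one SNP may contribute to several
genes.

# Track 2: componentwise likelihood-based boosting

`boost_fit()` builds a sparse multivariable model in small steps:

1. Fit the mandatory covariates by unpenalized partial likelihood; all L
   SNP coefficients start at zero.
2. In each step, with the current linear predictor held as offset, score
   every SNP by its one-dimensional *unpenalized* score statistic U²/I at
   gamma = 0.
3. Update the maximizing SNP (ties broken to the lowest column index, a
   deterministic convention) by the penalized one-step Newton estimate
   gamma = U/(I + lambda).
4. Re-estimate the mandatory coefficients by unpenalized Newton with the
   accumulated SNP contribution as fixed offset (a cheaper single-Newton
   variant is available via `mandatory_refit = "onestep"`).

Scoring by U²/I rather than by penalized likelihood improvement makes the
*selection* invariant to a SNP's coding variance — important for 0/1/2
genotypes, where variance differences between SNPs reflect allele
frequency, not prognostic relevance — while the *update* is still shrunken
by the penalty. The package tests both halves of this contract: recoding a
SNP leaves the selected index unchanged and rescales its update
reciprocally.

## Penalty and number of steps

The penalty only sets the step size; a larger lambda is compensated by
more steps. `lambda = "auto"` resolves to 9 × (number of events), which
makes each update roughly a tenth of the unpenalized Newton step — small
enough for stable stagewise behavior, large enough to keep path lengths
manageable. The real tuning parameter is the number of boosting steps,
chosen by `cv_select_steps()`: folds stratified by event status (so no
training fold is event-free), and for each candidate step count the
Verweij–van Houwelingen cross-validated partial likelihood — the full-data
partial log-likelihood at the fold-trained coefficients minus the held-in
part — summed over folds. This criterion needs no per-fold baseline-hazard
estimate, which suits the semiparametric model. Ties go to the smallest
step count. The default grid is 0..100; step 0 (no SNP at all) is always
on the grid, and selecting it is a legitimate outcome on weak data.

Each boosting step updates exactly one coefficient, so the number of
distinct selected SNPs never exceeds the step count, and the selection set
after m steps can be read off one fitted path — the evaluation harness
exploits this to get the CV-selected and fixed-step models from a single
run.

# Stability by subsampling

`stability_run()` draws `n_subsamples` (default 100) subsamples of size
floor(0.632 n) *without* replacement — bootstrap resampling with
replacement biases procedures with tuning parameters, because duplicated
subjects make resampled folds exchange information — and repeats the
*entire* selection procedure in each: the univariate track re-ranks and
re-applies the FDR cut on the subsample's own p-values, and the boosting
track re-runs cross-validation from scratch. Inclusion frequencies (IF)
count, per SNP and per gene, how many subsamples selected it; a gene is
counted once per subsample if any of its SNPs is selected (union
semantics). Empty selections are legal and recorded. Subsample runs are
seeded individually from the master RNG stream, so the report does not
depend on the order in which subsamples are processed.

# The synthetic-data generator

`sim_design()` encodes the generative model used throughout testing and
evaluation. Its defaults are the study conditions, not conveniences:

* genome: 100 genes × 300 blocks × 10 SNPs = 300000 SNPs; n = 500;
* genotypes: every SNP marginally Binomial(2, 0.4); within a block each
  SNP copies its left neighbor's genotype value with probability 0.75
  (0.50 for the SNP that opens a new block); the first SNP of each gene is
  independent, and genes are mutually independent. Copying the genotype
  *value* (not each allele separately) gives adjacent-SNP correlation
  exactly equal to the copy probability while preserving the binomial
  marginal — both properties are verified by Monte Carlo tests;
* effects: six informative SNPs, +0.5 at positions 2, 5, 9 (first block of
  gene 1), −0.5 at 33 and 37 (fourth block of gene 1) and at 3023 (third
  block of gene 2). The 24 non-informative SNPs sharing those three blocks
  form the "correlated noise" group; the remaining 299970 are
  "uncorrelated noise";
* survival: T = −log(U)/(h0 exp(eta)) with constant baseline hazard
  h0 = 0.1 (the exponential inversion implied by a constant hazard);
  censoring C ~ Uniform(0, 10); two clinical covariates (Bernoulli(0.5)
  and standard normal) are generated for adjustment with zero effect by
  default, so the adjustment machinery is exercised without confounding,
  and their effects are configurable for misspecification experiments.

Under these defaults the realized censoring fraction is about 0.6, not
0.5: conditional on eta, the censoring probability is
(1 − exp(−e^eta))/e^eta (since h0 · censor_max = 1), and averaging over
the genotype distribution gives ≈ 0.60 — the acceptance script recomputes
the empirical value (≈ 59.5%) alongside this closed form. A 50% rate
would require a shorter censoring window or a larger baseline hazard;
`censor_max` is exposed for such calibration, but the default stays at the
stated Uniform(0, 10).

What the generator does *not* emulate: MAF spectra (all SNPs share one
frequency), Hardy–Weinberg departures, population structure, genotyping
error and missingness, and realistic LD decay (correlation falls
geometrically within a block and vanishes between genes). Passing tests on
this design therefore demonstrate correct algorithmic behavior under
clean, block-structured LD — not performance guarantees on real cohorts.

# Evaluation harness

`run_study()` simulates replicates and scores each method by mean type I
error per noise group (the mean over replicates of the within-group
selected proportion) and power per informative SNP (the fraction of
replicates selecting it). Three methods are compared: the univariate FDR
screen, boosting with CV-selected steps, and boosting with a fixed 500
steps — the latter shows what happens when tuning is skipped (overfitting
into the correlated-noise group). `pairwise_r2()` provides composite-LD
r² on unphased genotypes for inspecting what the selections did to a
correlated region; no haplotype phasing is attempted since 0/1/2 data do
not carry phase.

# Numerical choices

* **Ties**: Breslow approximation throughout; simulated times are
  continuous (ties have probability zero), but read-in data with ties are
  handled consistently in the R and C code paths.
* **Risk sets**: subject k is at risk at event time t_i iff t_k >= t_i.
* **Stability**: within every risk-set computation the linear predictor's
  running maximum is subtracted before exponentiation.
* **Newton fitting**: start at zero (or a warm start inside the boosting
  refits), step-halving when the likelihood would decrease, convergence at
  max |update| < 1e-8 within 50 iterations; the one-dimensional screen
  kernel damps steps to |delta| <= 1 and declares monotone-likelihood
  divergence beyond |beta| > 15, reporting such SNPs as non-converged
  (`NA`) rather than returning silent garbage.
* **Degenerate inputs**: zero-variance SNPs, SNPs collinear with mandatory
  covariates and non-converged fits yield `NA` p-values with a warning
  count; missing genotypes are accepted on input but must be imputed
  explicitly (`impute_genotypes()`, rounded per-SNP mean) before modeling
  — imputation is never applied silently.
* **Seeding**: every stochastic routine consumes the R RNG stream, so
  `set.seed()` (or `--seed` on the command line) makes runs bit-for-bit
  reproducible; stability subsamples and study replicates derive per-unit
  seeds from the master stream so results are independent of execution
  order.

# Problem sizes used by the test suite

The full simulation study (300000 SNPs, 100 replicates, three methods) is
a cluster-scale computation. The package's test suite demonstrates the
same behavior at sizes chosen to keep a complete run on one CPU within
minutes: the univariate track runs at the full 300000-SNP design with 10
replicates; the three-method comparison runs on the `desk` preset genome
(10 genes, 30000 SNPs, identical block structure and informative SNPs)
with 20 replicates, a boosting CV grid of 0..60 steps and the fixed
500-step variant. At 30000 tests the BH threshold is less stringent than
at 300000, so absolute univariate rates drift upward relative to the
full design; the qualitative orderings between methods — boosting's lower
correlated-noise type I error, its higher power for the isolated
informative SNP on the second gene, and the overfitting of fixed-step
boosting relative to CV — are scale-stable and are what the acceptance
tests assert. Distributional checks (marginals, block correlations,
censoring) use n = 20000 subjects on small genomes, and the permutation
null-uniformity check uses 200 replicates at B = 99.

# Limitations

* Only Breslow ties, right censoring, time-fixed covariates; no
  stratification, no time-varying effects, no competing risks.
* The min-P permutation test inherits the resolution 1/B; genome-wide
  Bonferroni significance at K ≈ 20000 genes needs B well beyond 10^5,
  which is the practical cost ceiling of the approach.
* `offset_fast` is an approximation whose error grows with the strength of
  SNP–covariate dependence; use `joint` mode when the adjustment is
  delicate and L permits.
* Inclusion frequencies quantify stability but are deliberately not
  converted into error rates: at clinical-cohort power, formal
  stability-selection bounds would be too loose to be informative.
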