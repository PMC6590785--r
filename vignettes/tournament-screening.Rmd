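---
title: "Tournament screening of SNP markers for genomic prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tournament screening of SNP markers for genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tourney)
```

## The problem

Genome-wide selection predicts an animal's genomic breeding value
(GBV) from thousands of SNP dosages. Two features of such panels break
ordinary least squares: the number of markers far exceeds the number
of genotyped individuals (p >> n), and dense panels carry severe
multicollinearity — nearby markers segregate almost identically, and
some share a genotypic profile exactly. Penalized regressions such as
the Bayesian Lasso can be fitted in this regime, but a model built on
all markers tends to explain noise with marker effects: it predicts
its own training animals well and transfers poorly.

`tourney` implements a screening strategy that attacks both problems
before any genome-wide model is fitted: *tournaments* of small
multiple linear regressions. Each small regression group satisfies
n > p and (with high probability) contains no two markers in strong
linkage disequilibrium, so within a group classical inference is
sound.

## The tournament

Let S be the current marker set, initially all p markers. Each stage:

1. Partition S into K groups of approximately p_g markers
   (K = max(1, round(|S| / p_g)); sizes differ by at most one).
2. In each group, fit by ordinary least squares

   y_i = mu + sum_j x_ij beta_j + e_i,   e_i ~ N(0, sigma2),

   with x_ij in {0, 1, 2} the allele count of marker j in animal i.
3. Eliminate the group's worst marker: the one with the largest
   coefficient p-value, or, when a column is perfectly collinear with
   the columns before it (its effect cannot be estimated), one of the
   non-estimable markers chosen uniformly at random.
4. Pool the remaining markers and repeat with fresh groups until the
   target count survives.

The order of elimination is a genome-wide score: survivors first,
then markers from last-eliminated to first-eliminated. Extending a
finished screen to a larger marker count is therefore a subset
operation on `ranking()`, never a re-run.

Two grouping modes are provided. *Random* groups sample uniformly
from the pooled set. *Chromosome-conditioned* groups draw from each
chromosome proportionally to its current marker count
(largest-remainder allocation), so each group sees almost every
chromosome. Both are exposed because the way groups are formed is a
natural question about the procedure; in our simulations, as in the
study system the method comes from, the two modes select practically
the same markers.

### Numerical choices

* **Rank screening.** "Perfect collinearity" needs a floating-point
  definition. A column is declared non-estimable when its residual
  norm after projection on the retained columns to its left falls
  below `collinearity_tol` (default 1e-10) times the Frobenius norm of
  the group design — a tight proxy for the largest singular value at
  these tolerances. The screen runs left to right on the Gram matrix
  via an incremental Cholesky factorization, so the flagged column of
  a duplicated pair is always the later one, matching the
  "span of preceding columns" definition.
* **Ties.** Exact p-value ties eliminate the smaller |t|, then the
  lexicographically smaller marker ID. This keeps results independent
  of marker order in memory.
* **Final stage.** When a full stage would overshoot the target (fewer
  than `target` markers would remain), the stage's per-group
  candidates are ranked worst-first — non-estimable markers ahead of
  the largest p-values — and only the excess is removed. The survivor
  count is therefore exact. The source procedure leaves this case
  unspecified; trimming by worst p-value preserves its "worst goes
  first" principle.
* **Determinism and parallelism.** Every random choice inside a stage
  draws from a stream derived from (master seed, stage, group index),
  and per-group results are combined in group-index order. The result
  is a pure function of (data, seed): any parallel schedule would
  produce the identical `TournamentResult`. Missing dosages are
  rejected up front — quality control runs first.

## Effect estimation: the Bayesian Lasso

After screening (or as the comparison selector on the whole panel),
marker effects are estimated with the Park–Casella Bayesian Lasso:

* beta_j | tau2_j, sigma2 ~ N(0, sigma2 tau2_j)
* tau2_j ~ Exp(lambda2 / 2)
* lambda2 ~ Gamma(r, delta), defaults r = 1, delta = 0.1
* flat prior on mu, 1/sigma2 on the residual variance.

Dosage columns are centered internally and *not* scaled, so effects
stay on the dosage scale and the GBV of Eq. `GBV = X_s beta_s` can be
formed from raw dosages. The default chain — 4,000 iterations,
burn-in 2,000, thin 20, hence 100 retained draws — matches the
standard genomic-prediction usage of the method; tests use shorter
chains where only a functioning sampler is needed.

Two update schemes for beta are implemented and distributionally
equivalent (both are Gibbs samplers for the same posterior; their
agreement at small g is a test):

* `method = "joint"` draws the whole coefficient block from its
  multivariate-normal full conditional — a Cholesky solve for g <= n
  and an n-dimensional Woodbury-style solve for g > n that is exactly
  equivalent to the g-dimensional draw.
* `method = "scan"` (default) updates each beta_j from its univariate
  full conditional with residual updating. One sweep costs O(n g)
  rather than the O(n^2 g) of the wide joint draw, which is what makes
  whole-panel fits (g ≈ 12,000) and replicated selection studies
  practical on a single CPU; it is also the update used by the
  standard whole-genome regression packages in this field.

The degenerate conditional at beta_j ≈ 0 (the inverse-Gaussian mean
diverges) is handled by clamping the mean at 1e10; lambda2's Gamma
rate uses the current tau2 sum directly.

### HPD intervals and marker selection

`hpd_interval()` returns the shortest contiguous interval containing
ceiling(prob·m) of the m sorted draws; tied-width windows resolve to
the first (lowest). Selection rules:

* `select_top_by_estimate()` — the k markers with largest |posterior
  mean|, ties by marker ID; the full ranking backs marker-count
  sweeps.
* `select_by_hpd()` — markers whose HPD interval lies strictly on one
  side of zero. An interval touching zero counts as including it, the
  conservative reading.

The replicated final-selection pipeline
(`hpd_frequency_pipeline()`) chains tournament → Bayesian Lasso → HPD
selection, repeats it R times (default 100) and keeps markers selected
at least `freq_min` times (default 18, the worked threshold used with
R = 100 in the study this package operationalizes; it is exposed as a
free parameter because no optimality argument for it is known).

## The simulation framework

The generator emulates a post-QC, multi-chromosome SNP chip panel:

* Markers split near-evenly across chromosomes, positions increasing.
* Per sample and chromosome, two haplotypes from a first-order Markov
  chain: each allele copies its left neighbour with probability
  `ld_rho`, else is drawn fresh at the locus frequency (uniform in
  `maf_range`). Dosage is the haplotype sum.
* Defaults: `maf_range = (0.05, 0.5)` — a plausible frequency spectrum
  after a 3% MAF filter; `ld_rho = 0.7` — adjacent-marker correlation
  in the range reported for dense bovine chips after moderate
  subsampling.

Three planted-effect scenarios mirror the simulation study the method
was validated on: (1) 48 positive effects in four 12-marker clusters
on four chromosomes; (2) 48 positive effects, six per chromosome on
eight chromosomes, spaced at least 10 markers apart; (3) 250 small
effects of random sign spread over all chromosomes. Magnitudes are
drawn U[0.8, 1.2]·`magnitude` (scenarios 1–2) and
U[0.1, 0.4]·`magnitude` with random sign (scenario 3). Note that with
heritability held fixed, rescaling all effects rescales the residual
variance proportionally, so `magnitude` affects nothing but the trait
units — the identifiable quantities are the effect *counts*, the LD
structure, n, and h².

Phenotypes follow y = mu·1 + X beta + eps with mu = 100. The genetic
variance is the *empirical* variance of the realized X beta (the
identity is applied to the realized vector, not a theoretical
expectation), and the residual variance solves
h² = s2_G / (s2_G + s2_e), i.e. s2_e = s2_G (1 − h²)/h²: three times
s2_G at h² = 0.25, equal to it at 0.5, and exactly zero at h² = 1,
where no residual vector is drawn at all.

### What the generator does not emulate

The Markov haplotype model produces *local* LD that decays
geometrically (correlation ld_rho^d at lag d, range ≈ 3–5 markers).
Real dense-chip LD is block-structured and extends over tens of
markers, and real panels contain many exactly-duplicated genotypic
profiles genome-wide. Two consequences for interpreting tests run on
synthetic panels:

* perfect collinearity almost never arises inside random 25-marker
  groups here, while on real data it is common enough that the
  elimination rule has a dedicated branch for it;
* per-marker association signals are weaker than on a real map at the
  same h² (each QTL is tagged by few neighbours), so the measured
  screening-power margins of the tournament over chance and over the
  whole-panel Bayesian Lasso are conservative relative to what the
  real-map study reports. Passing those checks here shows the ordering
  of the methods, not the magnitude of the real-data gap.

## Quality control

The QC module reproduces the standard chip filters, in a fixed,
logged order: sample call rate (< 98% removed), two-sided sample
heterozygosity outliers (|het − mean| > 3 SD; the source procedure
does not state a direction, and two-sided is the conservative
convention), markers with any missing genotype, MAF below 3%
(computed from non-missing calls), fixed markers, and adjacent-marker
redundancy (exact profile equality with the retained marker
immediately to the left, never across chromosomes). Reason labels
use priority missing > fixed > maf, so an all-homozygous column
reports as "fixed" even though its MAF is also sub-threshold; the
removal *set* is unaffected by the labelling. MDS coordinates
(classical scaling of 1 − IBS) and a centroid-distance helper are
provided for outlier inspection, but no sample is ever auto-removed
on MDS evidence — that judgement stays with the analyst.

## Cross-validation design

`kfold_cv()` assigns samples to k contiguous blocks of a seeded
permutation (384 samples in 8 folds gives exactly 48 per fold). For
each fold and marker count m, effects are re-estimated on the
training folds only. The marker *ranking* consumed by the sweep can
be supplied two ways, because published sweeps of this kind are
ambiguous about it:

* a fixed full-data ranking (mirrors the published analyses; the
  ranking itself has seen the test phenotypes), or
* a selector function re-run inside every training fold — leakage-free
  and the recommended default; a taint test asserts that perturbing
  test-fold phenotypes leaves training-fold results bit-identical.

Without cross-validation, training correlation grows with m — the
overfitting direction — while held-out correlation favors a small
screened panel; both are asserted as orderings in the test suite, not
as magnitudes, since magnitudes depend on the synthetic LD described
above.

## Problem sizes used in the checks

The shipped checks run the method at the simulation study's full
panel scale (384 × 11,812, 10 chromosomes) for the tournament
contract, screening power (R = 20 phenotype replicates with a
2,000/1,000/10 chain for the whole-panel comparison fits), the
marker-count sweep {100, 500, 2,000, 11,812}, and the grouping-mode
comparison (10 seeds per mode). Replicate counts and chain lengths
for these studies are scaled to single-CPU sessions; the package
defaults (R = 100, 4,000/2,000/20) remain the recommended analysis
settings.

## Known limitations

* The generator's LD realism is deliberately minimal (see above);
  coalescent or pedigree simulation is out of scope.
* Dominance, epistasis, and contemporary-group correction of real
  phenotypes are out of scope; phenotypes are assumed pre-corrected.
* The Gibbs sampler ships no convergence diagnostics beyond a
  retained-draw minimum; the method's standard usage fixes the chain
  length a priori.
* The original top-k-per-group tournament variant is not implemented —
  only the worst-one-elimination variant this package is about.
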