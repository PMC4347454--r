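---
title: "Methods: parallel ICA for imaging-genetics fusion"
author: "picalink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel ICA for imaging-genetics fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`picalink` fuses two subject-aligned data matrices: fractional anisotropy
(FA) values over within-mask voxels, and additively coded SNP genotypes
(0/1/2 counts of the minor allele). Each modality is modeled as a linear
mixture

$$X_1 = A_1 S_1, \qquad X_2 = A_2 S_2,$$

with component maps in the rows of $S$ and per-subject loadings in the
columns of $A$. Unmixing is estimated by infomax ICA: with
$U = W X + W_0$ and the logistic squashing $Y = (1 + e^{-U})^{-1}$, the
entropy $H(Y)$ is ascended by the natural-gradient update
$\Delta W = \eta\,(I + (1 - 2Y)U^\top/m)\,W$ and
$\Delta W_0 = \eta\,\overline{(1 - 2Y)}$. The parallel variant adds the
squared Pearson correlation between one pair of loading columns to the
objective,

$$\max\; H(Y_1) + H(Y_2) + \mathrm{corr}(A_{1i}, A_{2j})^2,$$

so the two decompositions are nudged toward exposing a shared
subject-level factor. `constraint_update()` implements the closed-form
gradient of $\mathrm{corr}^2$ with respect to both columns (validated
against numerical differentiation in the test suite); because the
gradient of a *squared* correlation preserves sign, an anti-correlated
pair is driven toward stronger anti-correlation, never through zero.

### Assumptions

* Components mix linearly and are (super-Gaussian) independent within
  each modality; sparse spatial maps and sparse SNP weight vectors
  satisfy this well.
* Subjects are aligned across modalities and exchangeable under the
  null — the basis of the permutation test.
* The genotype dosage scale is treated as numeric; this is the standard
  additive coding and is what makes the linear mixture meaningful for
  the genetic modality.

## Algorithm mechanics and numerical choices

**Whitening.** Each modality is reduced along the subject dimension by
`pca_reduce()` (eigendecomposition of the subject-space covariance) so
that $W$ is square and invertible and $A = W^{-1}$ holds exactly in the
reduced space; the dewhitening map returns loadings to subject space.

**The constrained loop.** After each pair of infomax passes the
subject-space loadings are recomputed and the loading pair with maximal
absolute correlation identified. If it exceeds `constraint_threshold`
(default 0.3) the correlation-enhancement step is applied to that single
pair (`max_constrained_pairs = 1`) and propagated back by re-deriving
$W = A^{-1}$, keeping the model identity exact. The constraint step size
is `constraint_rate` (default 0.1) scaled internally by $(n-1)$ so that
its per-iteration effect on $\mathrm{corr}^2$ is roughly
subject-count-invariant.

**Endurance.** The entropy terms are the guardrail against manufacturing
correlation from noise: if an iteration's entropy drop is steeper than
`endurance` (default $-10^{-5}$) while the constraint is active, the
constraint is suspended for that iteration and its rate halved. The
mechanism (skip + halve) is this package's concrete reading of an
endurance bound on the admissible entropy slope; it is conservative and
easy to instrument.

**Annealing, convergence, degeneracy.** A modality's learning rate is
multiplied by `anneal_factor` (0.9) whenever its entropy surrogate
decreases; non-finite updates are rejected with the same annealing; a
singular intermediate $W$ (an overly aggressive step) is rolled back.
Convergence is declared when the relative Frobenius change of both
unmixing matrices falls below `convergence_tol` ($10^{-6}$) — with an
active constraint the system may instead reach a small steady-state
cycle, in which case the honest outcome is `converged = FALSE` at
`max_iterations` (512) with perfectly usable estimates; the flag is
reported, never silently absorbed.

**Standardization.** Component rows are scaled to unit variance (scale
absorbed into the loadings) and signs fixed so each component's
largest-magnitude weight is positive. This pins ICA's scale/sign
indeterminacy so that thresholded maps (`|Z| > 3.5`, strict) and top-5%
SNP sets (`floor(0.05 p)` largest absolute weights, ties broken by
ascending index) are reproducible.

**Model order.** The FA order uses the eigenvalue MDL criterion
(`estimate_ncomp_mdl()`), minimizing
$-n(p-k)\log(\mathrm{GM}/\mathrm{AM})$ of the trailing eigenvalues plus
$\tfrac12 k(2p-k)\log n$; equal eigenvalues give $k=0$ and ties go to the
smaller order. The SNP order uses run-to-run component consistency
(`estimate_ncomp_consistency()`): each candidate order is refit across
runs combining random initialization with a bootstrap resample of the
variables, components are greedily matched across runs by absolute
correlation, and the mean matched correlation is the score. The
bootstrap matters: PCA reduction is deterministic, so without it an
underfitted order is exactly as stable as the true one and the score
cannot peak; resampling perturbs the retained subspace and exposes both
under- and overfitting.

## The surrounding procedure

**Genotype QC** mirrors standard practice, in this order: subject call
rate, SNP call rate (both strict `> 0.9`), missing-call replacement from
the best high-LD proxy within a window (allele-aligned via the sign of
the dosage correlation; SNPs with an unfillable missing call are
removed), exact Hardy–Weinberg test in controls only (`p < 1e-6`
removed), and strict `MAF > 0.05`. Replacement precedes the
frequency-based filters so they see completed data. The HWE test
enumerates the conditional distribution of heterozygote counts given the
allele counts; the suite verifies it against an independent
recurrence-based enumeration for every table with up to 200 subjects.

**Ancestry correction** computes subject-space principal components of
the centered dosage matrix and removes those whose scores differ across
self-reported ethnicity by one-way ANOVA (Bonferroni over the
`max_pcs = 10` examined, family alpha 0.05). The number removed is an
outcome, not an input.

**Pre-filtering** keeps SNPs whose dosage differs between diagnostic
groups at uncorrected `p < 0.01` (Welch t-test by default; a pooled
trend-test variant is available), focusing the decomposition and keeping
the subject-to-variable ratio workable. On discrete genotype data the
t-test is slightly conservative at stringent thresholds — the suite
checks calibration on an independent-locus construction and bounds the
selection rate on generated cohorts, whose SNPs are deliberately
correlated within components.

**Site correction** regresses each voxel on site dummies and returns
residuals plus the voxel grand mean, equalizing per-site means exactly
while preserving grand means; a post-hoc site-by-diagnosis check on the
linked FA loading reports per-site group means, a direction-consistency
flag, and the interaction F-test.

**Inference.** The linked pair is summarized by raw and partial loading
correlation (OLS residualization on intercept + covariates; $t$
reference with $n - 2 - q$ df). The default adjustment set is site,
ethnicity, age and sex; a reduced age/sex set is equally valid and both
are exposed through the `use` argument, since either convention appears
in practice. Bonferroni correction uses the full pair family
($k_1 \times k_2$ tests). Because the constraint targets the top pair,
raw p-values of that pair are optimistically biased; the authoritative
null is the max-statistic permutation test, which shuffles the subject
order of one modality, re-runs the entire decomposition per permutation,
and counts `p = #{null >= observed}/n_perm` — so one exceedance in 5000
runs is exactly $2.00\times10^{-4}$, with no $+1$ correction.
Reproducibility uses diagnosis-stratified k-fold subset decompositions,
matching fold components to the full-data pair by absolute correlation
of weight vectors and reporting fold loading correlations and top-SNP
overlap ratios. A generic subgroup re-run supports single-ancestry or
other subset analyses.

## The synthetic cohort generator

`generate_linked_dataset()` emulates the study conditions end to end: 73
cases and 87 controls across 4 sites; nine FA and seven SNP components
with sparse, contiguous-run supports (disjoint across components — the
spatial realism of brain geometry is irrelevant to the algorithm, but
contiguous blobs make thresholded maps human-checkable); one planted
pair whose loading columns are built from empirically orthonormalized
Gaussian bases so their sample correlation equals the target (−0.37)
*exactly*, including opposite-direction group mean shifts (FA loading
higher in controls, SNP loading higher in cases — so the pooled link is
carried largely by the group contrast, and within-group correlations are
near zero). Observed FA is signal + per-site voxel offsets + Gaussian
noise. Genotypes discretize a continuous latent $A_2 S_2$ + noise per
SNP at quantile cutpoints matching Hardy–Weinberg proportions at a MAF
drawn from `maf_range`; this preserves the linear structure the
decomposition assumes while producing legal 0/1/2 marginals, at the cost
of attenuating the genetic signal exactly as real discretization would.
Group genetic effects enter through the loading shift, not through
allele-frequency resampling. All randomness flows from one seed through
labeled substreams, so every output is bit-reproducible.

Default parameter choices: `group_effect_fa = 1.0` gives a loading group
difference around $p \sim 10^{-8}$ at $n = 160$, and
`group_effect_snp = 1.2` a somewhat stronger genetic one, matching the
qualitative pattern of a diagnosis-driven link; `noise_sd_fa = 0.3` and
`site_effect_sd = 0.3` put single-voxel signal-to-noise near 10:1 for
active voxels; `sparsity_fa = 0.05` and `sparsity_snp = 0.1` give
blob/panel sizes typical of thresholded maps. `missing_rate = 0` by
default because the panel represents analysis-ready post-QC data and the
generated loci carry no linkage disequilibrium that could serve as
replacement proxies; QC tests enable missingness explicitly.

What the generator does **not** emulate: diffusion tensors or
acquisition physics, registration/smoothing artifacts, realistic LD
block structure, population-genetic allele-frequency differentiation
(ancestry tests construct their own stratified populations), or
clinical-scale covariates. Passing recovery tests therefore demonstrates
algorithmic correctness under the model's assumptions — not performance
on any particular real cohort.

## Problem sizes used in the test suite

The suite exercises the method at sizes chosen to make each property
measurable with comfortable margins: planted-pair recovery at full study
scale (160 × 5000 voxels and 1000 SNPs, ten seeds); permutation
calibration on 20 null cohorts of 60 subjects × 300 voxels × 200 SNPs
with 200 permutations each under a declared reduced-iteration profile
(30 iterations); MDL recovery on 100 simulations of a rank-3 signal at
SNR 10; separation quality on 5-source super-Gaussian mixtures over 160
channels; and exhaustive HWE oracle comparison over all genotype tables
with up to 200 subjects.

## Known limitations

* The correlation-enhancement gradient is this package's own derivation
  of the published objective; no bit-equivalence with any external
  toolbox implementation is claimed.
* With an active constraint the alternating system may cycle rather than
  meet the strict weight-change tolerance; results are stable but the
  convergence flag stays `FALSE`.
* The permutation test re-runs the full decomposition per permutation;
  at 5000 runs on study-scale data this is hours of compute, which is
  why a reduced-iteration profile is supported (and flagged in the
  result).
* Raw p-values of the constrained pair are anti-conservative by design;
  use the permutation p for inference on the top pair.
* The consistency-based order estimator scores stability, which peaks at
  the true order only when sources are genuinely distinguishable; on
  weak-signal data it degrades gracefully toward small orders.
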