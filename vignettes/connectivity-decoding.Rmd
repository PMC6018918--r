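---
title: "Methods: connectivity mapping and transcriptomic decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity mapping and transcriptomic decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdecode)
library(dplyr)
```

fcdecode implements a complete analysis chain for two-group resting-state
fMRI studies in the mouse and for the transcriptomic interpretation of the
connectivity differences they reveal. This vignette is the package's
methods account: the models and procedures, the parameters that matter and
their defaults, what the synthetic-data generators do and do not emulate,
the numerical choices, and the known limitations.

## 1. The scientific problem

Spontaneous, slow (< 0.1 Hz) fluctuations of the blood-oxygen-level-
dependent (BOLD) signal are correlated between brain regions that are
functionally connected. Comparing those correlations between a mutant and
a wildtype group localizes circuits whose coupling a mutation alters. Once
a pair of over-connected regions is found, a separate question follows:
*which genes are preferentially expressed in exactly those regions?* The
package answers both questions with a pipeline of five stages:

1. **Preprocessing** of each subject's 4D BOLD run;
2. **Connectivity mapping** (global "r score" maps and seed-based maps);
3. **Group inference** with permutation family-wise-error (FWE) cluster
   correction;
4. **Transcriptomic decoding** of a hotspot region pair against a regional
   gene-expression-energy matrix, with a random-pair specificity control;
5. **Gene-set overlap** statistics (Fisher's exact test and odds ratio)
   for differential-expression results against curated risk-gene lists.

Every input has a seeded synthetic generator, so the whole chain is
testable end to end with planted ground truth.

## 2. Preprocessing model

`preprocess_bold()` applies the stages in a fixed order — trim, despike,
nuisance regression, spatial smoothing, band-pass — with these defaults:

| stage | parameter | default | unit | rationale |
|---|---|---|---|---|
| `trim_volumes()` | `n_trim` | 20 | volumes | discard T1-equilibration transients at acquisition start |
| `despike()` | `c1`, `c2` | 2.5, 4.0 | robust SDs | onset and cap of spike compression |
| `regress_nuisance()` | — | intercept + ventricular + 6 motion | — | remove global physiological and motion-locked variance |
| `smooth_spatial()` | `fwhm_mm` | 0.6 | mm | spatial SNR at mouse cortical scale |
| `bandpass_filter()` | `low_hz`, `high_hz` | 0.01, 0.1 | Hz | resting-state fluctuation band |

**Despiking.** No universal despike algorithm exists; we use a
per-voxel quadratic detrend, residuals expressed in robust SD units
(1.4826 × MAD), and hyperbolic compression of suprathreshold residuals,
$s' = c_1 + (c_2 - c_1)\tanh\!\big((|s| - c_1)/(c_2 - c_1)\big)$,
which leaves residuals below $c_1$ untouched and caps any spike at $c_2$
robust SDs. The constants are exposed because other implementations use
different envelopes; ours makes the compression contract exactly testable.

**Nuisance regression.** Each voxel is replaced by its least-squares
residual against `[intercept | ventricular mean | 6 motion traces]`.
The intercept is always included: downstream correlation is mean-invariant
and the intercept makes the perfect-fit case exact. A rank-deficient
design is an error that names the collinear columns rather than silently
dropping one. Volume realignment ("motion correction") is out of scope:
synthetic data are generated aligned, and motion enters the model only
through the regressors.

**Smoothing.** Separable Gaussian with
$\sigma_{mm} = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ converted to voxel units
per axis, and *mask-normalized*: the data are multiplied by the mask,
convolved, and divided by the convolved mask, so constants are preserved
inside the brain and out-of-mask values neither bleed in nor get modified.

**Band-pass.** A forward-backward (zero-phase) Butterworth of order 2 per
pass, applied to mean-removed series with odd-reflection padding to tame
edge transients. Order and family are artifact choices — only the window
is scientifically given — and are exposed as parameters. At TR 1.2 s the
Nyquist frequency is ≈ 0.417 Hz; a high cut at or above it is an error.
Measured on 512-point sinusoids, the filter keeps ≈ 98% amplitude at
0.05 Hz and ≈ 2% at 0.2 Hz (the acceptance script recomputes both). Note
that a finite band-passed window is not exactly mean-free; residual voxel
means are a small fraction of the fluctuation SD.

`fluctuation_amplitude()` returns the temporal SD of an ROI-mean
band-passed signal — the anesthesia-depth quality-control readout; for a
unit sinusoid it is $1/\sqrt{2}$.

## 3. Connectivity mapping

**Global maps.** "Global connectivity" is not formally defined in most
reports; we define the r score at voxel $v$ as the self-excluded average
correlation with all other in-mask voxels, averaged in Fisher-z space and
back-transformed:
$r(v) = \tanh\big(\tfrac{1}{|V|-1}\sum_{u \neq v} \operatorname{atanh}
\rho_{uv}\big)$.
Fisher-z averaging variance-stabilizes the mean; the back-transform keeps
the reported quantity an r score. Zero-variance voxels are excluded from
both the target and the reference set, with a message. On grids of ≤ 30
voxels the implementation is tested to equal the brute-force all-pairs
computation to 1e-10.

**Seed maps** correlate each voxel with the mean series of a (possibly
bilateral) seed mask. **Regional strength** averages any map over the
in-mask voxels of each parcellation region, returning a tibble.

**Group inference.** Group maps are compared voxelwise with a
pooled-variance two-sample t statistic on Fisher-z maps
(df = $n_a + n_b - 2$; positive t = group A > group B). Cluster-level FWE
control is nonparametric: suprathreshold voxels ($|t|$ above the
cluster-defining threshold, positive and negative tails clustered
separately under 6-connectivity) form clusters whose corrected p is the
proportion of group-label permutations whose *maximum* cluster extent
reaches the observed extent, with the +1 correction in numerator and
denominator. When the requested permutation count reaches the number of
distinct relabelings, the null is enumerated exhaustively (924
relabelings at 6+6, 70 at 4+4), making the result seed-free. Permutation
was chosen over parametric random-field theory because it is exact under
exchangeability and needs no smoothness estimate.

**The cluster-defining threshold (CDT).** The default is the two-sided
critical t at the groups' actual df (`critical_t(df)`; 2.06 at df = 24 —
reproduced as a constant, not derived from any cohort, since a printed
"$t_{24}$" with 42 subjects cannot be reconstructed). The CDT is a real
analytic choice, and cluster-*extent* inference is known to lose power at
lenient CDTs: when an effect is strong and spatially homogeneous, every
relabeling that shares most of one group still pushes the whole affected
block above a low threshold, so the null maximum extents tie with the
observed extent and the corrected p saturates near the fraction of such
relabelings. We observe exactly this on the scaled-down synthetic cohort:
at CDT = `critical_t(10)` ≈ 2.23 the planted effect yields peak |t| ≈ 8.7
yet corrected p ≈ 0.053, while at the stricter voxelwise p = 0.01
(CDT ≈ 3.17) the observed clusters dominate the null (p ≈ 0.008) and
recover the planted pair with Dice ≈ 0.97. The recovery experiments in
the test suite and the acceptance script therefore use the stricter
CDT — the standard recommendation for small samples — and we flag the
saturation behaviour as an inherent property of extent-based inference on
homogeneous effects, not of this implementation.

`fdr_adjust()` (Benjamini–Hochberg step-up) is provided for
multiple-comparison control across regions or annotation sets.

## 4. Transcriptomic decoding

The decoding asks whether gene sets are over-represented among genes
preferentially expressed in a hotspot region pair.

**Expression energies.** `expression_energy_by_region()` averages
per-gene expression-energy volumes under a parcellation (the regional
summary convention of atlas-scale in-situ-hybridization data); real data
can also be supplied pre-summarized as TSV. `normalize_by_total()`
divides each gene's row by its total over regions, removing probe-affinity
scale; zero-total genes are dropped (division undefined, no ranking
information), and retained rows sum to 1 (±1e-9).

**Two candidate selections** over a region pair $(r_1, r_2)$:

* *intersection mode* — genes in the top $\lceil qN \rceil$ (default
  $q = 0.20$) of both regions' normalized values, ties broken by gene id;
  tested against each annotation set with the fixed hypergeometric upper
  tail;
* *ranked mode* — genes ranked by the pair sum
  $x_{g,r_1} + x_{g,r_2}$ (the L1 score, which also favors genes very
  high in just one region), tested with the minimum-hypergeometric (mHG)
  statistic.

**The mHG statistic and its exact p.** For a ranked list of $N$ genes
containing $B$ targets, with $b(n)$ targets in the top $n$,
$s = \min_{1 \le n \le N} P\big[X \ge b(n)\big]$, $X$ hypergeometric
$(N, B, n)$ — the optimal threshold is found per set, automatically. The
minimum over thresholds makes $s$ itself anti-conservative, so the exact
p corrects it: the probability, over uniform random orderings, that the
minimum tail is ≤ $s$. We compute it by dynamic programming on the lattice
of (prefix length, targets seen): probability mass moves with
hypergeometric-path transition probabilities
$P(\text{take}) = (B-b)/(N-n)$, any cell whose tail is ≤ $s$ absorbs its
mass, and the p-value is one minus the surviving mass. The DP is $O(NB)$,
runs in plain probability space (all quantities in [0, 1]), and is tested
to equal full-ordering enumeration exactly for $N \le 8$, to match a
10,000-shuffle Monte-Carlo estimate within 3 SE, and to respect the
bounds $s \le p \le \min(1, Ns)$.

The enrichment universe is the set of genes retained in the normalized
matrix; within each selection mode, p-values are BH-FDR corrected across
annotation sets. `random_pair_control()` repeats the entire decoding on
`n_pairs` (default 10) region pairs drawn uniformly without replacement,
excluding the focal pair, and reports per-pair significant-set counts —
the specificity control: a real signal should make the focal count exceed
the controls.

## 5. Gene-set overlap

`build_contingency()` crosses a DEG set against a risk list within an
*explicit* universe (no default universe is invented — published overlap
statistics are frequently irreproducible precisely because the universe
is unstated). `fisher_exact_or()` computes the two-sided exact p by
point-probability ordering (summing hypergeometric point probabilities ≤
the observed one, the `fisher.test` convention, implemented by direct
log-space summation over the support and cross-checked against
`fisher.test` in the tests) and reports the sample (cross-product) odds
ratio $ad/bc$ by default, with the conditional-MLE estimate behind
`or_method = "conditional_mle"`. The two OR conventions differ and
published values rarely say which was used, so neither is claimed to
match any particular printed number.

## 6. Synthetic-data generators

The generators define the study conditions for all tests; they are
first-class, seeded, pure functions of their configuration.

**BOLD cohorts** (`generate_bold_cohort()`). Defaults: 6 + 6 subjects
(scaled down from the 23 + 19 of the motivating study design), 20×20×4
voxels of 0.2×0.2×0.5 mm, 220 timepoints at TR 1.2 s (so 200 remain after
trimming 20), AR(1) noise with coefficient 0.3 (the minimal temporally
correlated model; real BOLD autocorrelation is unknown for this design).
Signal model per voxel, scaled to fluctuation SD 2 over a baseline of
100:

$$x_v(t) = \sqrt{|\rho|}\,g(t)\,\sigma_v + \sqrt{\lambda}\,h_{R(v)}(t)
  + \sqrt{1 - |\rho| - \lambda}\,e_v(t)$$

where $g$ is the planted cross-pair latent (weight nonzero only in the
two planted regions, with $\sigma_v = \mathrm{sign}(\rho)$ in the second
region so negative plantings work), $h_R$ is a per-region latent giving
every parcel the within-region coherence real cortex shows
($\lambda$ = `local_corr`, default 0.2), and $e_v$ is voxel noise — all
unit-variance AR(1). Expected correlation between voxels across the
planted pair is exactly $\rho$, which the tests verify empirically
(±0.1 at 2000 timepoints). A central ventricular block carries a slow
(AR 0.95) nuisance signal at `nuisance_amplitude` (default 1 fluctuation
SD), leaked brain-wide at 30% amplitude so ventricular regression has
something real to remove; motion traces are smoothed random walks
(3 translations, 3 rotations at 1/10 amplitude). Not emulated: scanner
spike artifacts (tests inject their own), k-space/EPI physics, anatomical
contrast, genuine subject motion of the image grid, and spatially
heterogeneous effect profiles — planted blocks are homogeneous, which is
what makes extent-based cluster inference saturate at lenient CDTs
(section 3). Passing tests therefore demonstrate correctness of the
estimators under a controlled correlation structure, not performance on
real acquisition artifacts.

**Parcellations** (`generate_parcellation()`) recursively bisect the grid
into the requested number of rectangular blocks — every region is a
6-connected block of at least one voxel — then permute labels with the
seed. **Expression matrices** (`generate_expression_matrix()`) draw
baseline energies as a per-gene log-normal level (sdlog 0.5, emulating
probe-affinity spread) times mean-1 gamma noise (shape 5), then multiply
the planted set by `enrichment_effect` (default 5) in the two focal
regions; decoy sets are size-matched draws from the remaining genes.
**DEG tables** (`generate_deg_table()`) realize an exact 2×2 overlap
between a DEG set and a risk list inside a universe, dressed with the
`gene_id / log2fc / pvalue / padj` schema (DEGs get `padj` < 0.05, about
two-thirds down-regulated, mirroring the neonatal-cortex pattern the
schema emulates).

## 7. Numerical choices and degenerate inputs

* Correlations of exactly ±1 between distinct voxels propagate as ±Inf
  through internal z-averaging and return ±1 after `tanh` — no clipping
  inside `global_connectivity_map()`; the user-facing `fisher_z()` clips
  at ±(1 − 1e-7) with a warning.
* Zero-variance voxels: excluded from correlation, reported via message.
* mHG significance cells are matched with a 1e-10 relative tolerance so
  ties at the observed statistic count as extreme.
* Fisher two-sided summation uses a 1e-7 relative tolerance on the
  observed point probability, as `fisher.test` does.
* Cluster p-values use the +1/(K+1) permutation convention; at exhaustive
  enumeration the identity relabeling and its complement are always
  counted, so the smallest attainable p at 6+6 is 3/925.
* Degenerate 2×2 margins return p = 1 with `NaN` odds ratio and a
  warning; `b·c = 0` with `a·d > 0` returns `Inf`.
* Ties in gene selection and ranking always break by gene id, ascending,
  so every selection is deterministic.

## 8. Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run the pipeline at the
scaled-down defaults: recovery on the 6+6 cohort (1600 voxels, 220
timepoints, exhaustive 924-relabeling null); null calibration of the FWE
stage on 200 cohorts of 4+4 subjects on an 8×8×2 grid with 120
timepoints (exhaustive 70-relabeling null); decoding on 500 genes × 20
regions with a 50-gene planted set and 9 decoys, with 100 gene-label
permutations for the null and 10 random control pairs. These sizes were
chosen so the full chain demonstrates its statistical properties at
desk scale; all of them are configuration, not constants.

## 9. Known limitations

* No image registration, slice-timing, fieldmap, or physiological
  regressors; inputs are assumed spatially aligned.
* Cluster inference offers extent as the cluster statistic; mass-based
  statistics, which do not saturate on homogeneous strong effects, are
  not implemented.
* The decoding takes annotation sets as given (no ontology-graph
  propagation) and its universe is the expression matrix, which on real
  atlas data is a biased subset of the genome.
* The sample odds ratio and the conditional-MLE odds ratio can differ
  appreciably on small tables; comparisons with published values must
  know which convention was printed, and usually cannot.
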