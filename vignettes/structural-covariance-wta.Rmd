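---
title: "Winner-take-all structural covariance: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winner-take-all structural covariance: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnwta)
```

## The model

Structural covariance networks treat the across-subject correlation of
regional gray-matter volume (GMV) as a connectivity-like quantity: regions
whose volumes rise and fall together across a cohort are taken to share
developmental or degenerative influences. This package implements that idea
for cortico-striato-thalamo-cerebellar circuits in a three-arm design (two
generalized-seizure epilepsy syndromes, GE-GTCS and FE-FBTS, plus healthy
controls):

1. **Seeded covariance.** The cortex is divided into five non-overlapping
   lobes. For one group, the seed signal of lobe $l$ is the per-subject
   mean GMV over the lobe mask. For each voxel $v$ of a target structure
   (striatum, thalamus, cerebellum), the coefficient is the partial
   correlation of seed and voxel GMV given the other four lobes' means and
   total intracranial volume (TIV). Conditioning on the other lobes
   isolates lobe-specific covariance from the global GMV factor;
   conditioning on TIV removes head-size confounding.
2. **Winner-take-all (WTA).** Each structure voxel is labeled with the
   lobe of its highest *signed* coefficient, partitioning each structure
   into five territories per group. Voxels whose coefficients are all
   negative remain labeled (the partition is total); an absolute-value
   winner rule is available behind `absolute = TRUE` but is off by
   default, because the signed maximum is the natural reading of "highest
   correlation coefficient". Exact ties (a measure-zero event in floating
   point) go deterministically to the lowest lobe id and are counted on
   the map object.
3. **Permutation comparisons.** Winning-voxel counts per lobe are compared
   between two groups with a group-label permutation test: labels are
   reshuffled with group sizes preserved and *both* WTA maps are
   recomputed per permutation, so the null respects every stage of the
   estimator. P-values use the add-one estimator
   $(1 + \#\{|T^\pi| \ge |T|\})/(B+1)$, two-sided, which cannot return 0.
4. **The 20-node network.** Node signals are the five cortical lobe means
   plus, for each structure, the five WTA-subregion means of that group.
   Each edge is the pairwise partial correlation of two node signals given
   TIV. Group differences per edge use the Fisher-z difference with the
   same full-recomputation permutation scheme (pseudo-group subregions are
   re-derived every permutation, keeping the null exchangeable), followed
   by the false-positive-adjustment (FPA) omnibus: per-edge findings are
   only reported when the number of edges below $\alpha$ exceeds
   $\alpha \cdot 190$, the count expected by chance.
5. **Duration modulation.** Within a patient group the model
   $GM_{target} = \beta_0 + \beta_1 GM_{seed} + \beta_2 D +
   \beta_3 GM_{seed} D + \beta_4 TIV$ is fitted by OLS, with disease
   duration $D$ in months; $\beta_3$'s t statistic measures how duration
   modulates the covariance. Between the two patient groups the design
   adds Group (0/1, GE-GTCS = 1) and all its interactions, and the triple
   interaction $\beta_7$ carries the syndrome difference in modulation.
   Scans cover, for each lobe's subnetwork, the 12 directed (seed, target)
   pairs among cortex, striatum, thalamus, cerebellum — 60 fits per scope.
6. **Voxelwise statistics.** A three-group ANOVA (covarying TIV, age,
   sex), the partial correlation of voxel GMV with duration per patient
   group (covarying TIV, sex, age), and the group-by-duration slope
   interaction over both patient groups. Cluster-extent family-wise error
   control is by permutation rather than Gaussian-random-field theory:
   random-field smoothness estimation is a tooling-specific step, whereas
   permutation of the Freedman-Lane residuals is exact under
   exchangeability and makes no smoothness assumptions. This is a
   deliberate, documented divergence from SPM/DPABI-style correction.

## Interpretation conventions

* An intercept is always included even though compact model notations often
  omit it; the residual degrees of freedom ($n-5$ within group, $n-9$
  between groups) follow from intercept plus listed terms, and match the
  way published (t, p) pairs in this literature convert.
* Modulation p-values are one-tailed, $P(T_{df} \ge |t|)$, reported with
  the estimate's sign; published modulation tables in this literature pair
  signed t statistics with one-tailed probabilities (e.g. t = −2.284 at
  df = 106 ↦ p = .012, t = −2.966 at df = 213 ↦ p = .002), and the
  two-tailed alternative is available via `two_tailed = TRUE`.
* Duration enters uncentered, in months. Because all lower-order terms are
  present, the interaction t statistics are invariant to mean-centering of
  seed and duration and to affine recoding of Group — both invariances are
  tested to 1e-8.
* The between-group modulation scan and patient-vs-patient network
  comparisons need a single subregion definition covering both groups; the
  package uses the healthy-control WTA maps as that reference (unbiased
  with respect to the patient contrast), while within-group scans use the
  group's own maps. Both choices are arguments, not constants.
* The network stage conditions on TIV only, matching the nuisance set of
  the map stage; age/sex can be appended through the `covariates` argument
  of `build_network()`.

## The synthetic cohort generator

Real morphometry cohorts for this design are not publicly deposited, so the
package ships a generator (`generator_config()`, `generate_atlas()`,
`generate_cohort()`) that emulates the study conditions and returns ground
truth for every planted feature. The atlas is a spherical cortical shell
split into five angular sectors plus three interior ellipsoids, each
partitioned into five contiguous angular territories. Subject volumes
follow a latent-factor model: per-subject lobe factors
$f \sim MVN(0, C)$ with exchangeable correlation 0.3 drive both the
cortical voxels of each lobe (loading 0.05) and the subcortical voxels of
the territory assigned to that lobe, with coupling
$w_0(g,r,l) + w_1(g,r,l)\,d$ that may depend on group and duration.
Additive pieces: a TIV confound (2e-4 per ml around a 1500 ± 120 ml
distribution), optional per-month atrophy slopes per region and group,
and spatially smoothed Gaussian noise (marginal SD 0.04, 6 mm FWHM),
clipped to [0, 1] last. Demographics mirror the study scale: three arms
(default 40, study scale 111 per arm), a fixed 71:40 male:female ratio,
age 26 ± 7.5 years, duration truncated-normal with mean 83 and SD 94
months (the SD implied by the published SEM at n = 111), bounded below at
1 month.

Because coupling enters through the latent lobe factor rather than voxel
means, across-subject covariance *is* the generative mechanism — the WTA
estimator is tested on exactly the quantity it estimates. Determinism: one
sub-stream per subject derived from the config seed, so earlier subjects
are unchanged when the cohort grows.

What the generator does **not** emulate: cortical folding, hemispheric
asymmetry, scanner artifacts, segmentation error, and spatial
normalization residuals. Passing tests therefore demonstrate estimator
correctness and calibration under the stated covariance model, not
robustness to real-data preprocessing failures.

## Calibration and recovery studies

The test suite and `scripts/acceptance.R` run three kinds of simulation,
whose regimes are themselves design choices:

* **Null calibration** (200 replicates, 199 permutations, 16³ grid,
  20 subjects/arm) uses a *low-SNR* variant (coupling 0.02, noise SD 0.06,
  identical across groups). Under the default high-SNR coupling the WTA
  labels are essentially deterministic, the count statistic degenerates to
  0 and every permutation p is 1 — valid but maximally conservative, so no
  rejection-rate check could be informative. In the low-SNR regime all
  three procedures (map count test per lobe, network edge test, cluster
  FWE) show rejection rates statistically compatible with the nominal .05.
* The **FPA omnibus** is an expected-count screen, not an $\alpha$-level
  test: under the null, with ~190 weakly dependent edges and per-edge rate
  just under .05, the count exceeds its expectation in roughly a third of
  replicates. The suite therefore asserts per-edge calibration and the FPA
  arithmetic, not a 5% omnibus rate.
* **Recovery** uses the default coupling (0.06, voxel SNR ≈ 1.5, in-territory
  partial correlation ≈ 0.8) for WTA territory recovery, and a planted
  coupling slope of −1e-4 per month (baseline raised to 0.12 so the
  coupling stays positive over the duration range) for the modulation
  models at the study's n = 111 per arm. The slope magnitude was chosen so
  the coupling loses roughly its baseline over ~100 months — a clearly
  nonzero but not overwhelming effect (within-group t statistics around
  −4).
* **Localized-effect cluster recovery** switches off the latent factors
  and noise smoothing: with lobe-factor coherence on, the max-cluster null
  is dominated by whole-lobe pseudo-clusters (hundreds of voxels), which
  correctly reflects that cluster-extent correction has little power for
  effects smaller than the data's intrinsic coherence scale.

Problem sizes (16³ grids, 20-111 subjects per arm, 199-499 permutations)
keep any single study under a few minutes on one CPU; the study-scale
defaults (32³ grid, 5000 permutations) are the intended settings for real
use.

## Numerical choices and degenerate inputs

* Gaussian smoothing uses $\sigma = FWHM/(2\sqrt{2\ln 2})$ per axis in
  voxel units, a separable kernel truncated at $4\sigma$ and renormalised,
  and zero-padding — the brain-imaging convention where outside-brain is
  zero gray matter; mass is lost only at the array edge, and the smoothed
  noise field in the generator is variance-restored analytically via the
  kernel's sum of squares.
* Partial correlation residualises both variables on [1, Z] via QR;
  rank-deficient designs are an error. A variable that is *constant* is a
  degenerate error; a variable fully absorbed by the covariates (residual
  sum of squares below 1e-12 of its variance) returns a partial
  correlation of exactly 0 — the covariates explain it, so no partial
  signal remains.
* Cluster membership uses 26-connectivity (the 3D morphometry standard),
  computed on the sparse suprathreshold set via neighbor hashing; labels
  are renumbered by first appearance, so voxel traversal order cannot
  affect the result.
* Permutation p-values can never be 0 (add-one estimator) and are bounded
  below by $1/(B+1)$.
* All OLS fits refuse collinear designs rather than silently dropping
  terms.

## Known limitations

* The generator's duration distribution has a heavy right tail (truncated
  normal with SD larger than its mean); real duration distributions may be
  more skewed still, and the modulation models are linear in duration by
  design.
* Cluster-extent correction is calibrated under exchangeability of
  Freedman-Lane residuals; strong heteroscedasticity between groups would
  weaken that guarantee.
* Subregion nodes can be empty when a lobe wins no voxels in a structure;
  such nodes are reported missing and excluded from edges rather than
  imputed.
* The pipeline analyses synthetic cohorts as generated; the 8 mm FWHM
  pre-smoothing stage applies when volumes are loaded from a cohort
  directory of per-subject NIfTI files.
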