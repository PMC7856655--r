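# scnwta — winner-take-all structural covariance networks

`scnwta` implements a structural covariance network (SCN) analysis of
voxel-based morphometry data for cortico-striato-thalamo-cerebellar
circuits, aimed at studies of generalized-seizure epilepsy syndromes
(genetic generalized epilepsy with tonic-clonic seizures, GE-GTCS, and
focal epilepsy with focal-to-bilateral tonic-clonic seizures, FE-FBTS,
against healthy controls), together with a synthetic cohort generator that
makes every step testable against planted ground truth.

## The method

**Winner-take-all mapping.** The cortex is divided into five lobes
(frontal, motor/premotor, somatosensory, parietal/occipital, temporal).
For each group, each voxel *v* of the striatum, thalamus and cerebellum is
correlated across subjects with the mean gray-matter volume (GMV) of each
lobe *l* by partial correlation,

    r_l(v) = pcor( GMV_lobe_l , GMV_v | GMV of the other 4 lobes, TIV ),

and labeled with the lobe of the highest coefficient ("winner take all"),
partitioning each structure into five subregions per group.

**Permutation comparisons.** Winning-voxel counts per lobe are compared
between groups by permutation: group labels are reshuffled (sizes
preserved), both winner-take-all maps recomputed per permutation, and a
two-sided p-value computed as (1 + #{|null| ≥ |obs|}) / (n_perm + 1). The
20-node network (5 cortical lobes + 3×5 subregions) is built per group by
pairwise partial correlation given TIV; edges are compared between groups
by the Fisher-z difference under the same full-recomputation permutation
scheme, with a false-positive-adjustment omnibus (significant edges must
outnumber `alpha × 190`).

**Duration modulation.** Within a patient group,

    GM_target = b0 + b1·GM_seed + b2·Duration + b3·GM_seed×Duration + b4·TIV

where the t statistic of `b3` measures how disease duration modulates the
seed-target covariance; between the two patient groups the model adds
Group (0/1, GE-GTCS = 1) and all its interactions, and the triple
interaction `b7 = Group×GM_seed×Duration` measures the syndrome difference
in that modulation. P-values are one-tailed, `P(T_df ≥ |t|)`, with
direction carried by the sign.

**Voxelwise statistics.** Three-group ANOVA (covarying TIV, age, sex),
partial correlation of GMV with duration per patient group, and the
group-by-duration slope interaction, each correctable by permutation
cluster-extent FWE (26-connectivity, Freedman-Lane residual permutation).

## Worked example

```r
library(scnwta)

# a three-arm synthetic cohort with planted territory coupling
cfg <- generator_config(grid = 16, n_per_group = 20, seed = 3)
sim <- generate_cohort(cfg)
ds  <- sim$dataset

m <- wta_structure_map(ds, "striatum", group = "HC")
count_labels(m)
#>            frontal     motor_premotor      somatosensory parietal_occipital
#>                  4                  5                  5                  5
#>           temporal
#>                  5
mean(m$winner_label == true_territory(sim, "striatum"))
#> [1] 1

demographic_balance(sim$cohort)
#> Demographic balance
#>   age      one-way ANOVA  F(2, 57) = 0.469, p = 0.628
#>   sex      chi-square     X2(2) = 0.000, p = 1.000
#>   duration two-sample t   t(38) = 0.061, p = 0.952
```

The 24 striatal voxels split 4/5/5/5/5 across the five lobe territories and
every voxel is assigned to its true generating lobe; the three arms are
demographically balanced by construction (identical 71:40 sex ratio, shared
age and duration distributions).

The `analysis/` directory runs the full study as numbered scripts —
`01_simulate.R` (cohort), `02_demographics.R`, `03_wta_maps.R` (maps,
counts, permutation comparisons), `04_network.R` (20-node networks + FPA),
`05_modulation.R`, `06_vbm.R` (voxelwise maps + cluster correction) — each
writing its tables under `results/analysis/`. On the default planted
configuration the motor-subnetwork cortex→striatum modulation comes out at
t = −3.50 (one-tailed p ≈ .0005) in GE-GTCS versus t = −1.26 (p ≈ .11) in
FE-FBTS, matching the planted coupling slopes (−1.0e-4 vs −0.5e-4 per
month), and the duration correlation is negative in the cerebellum
(mean r ≈ −0.25) where atrophy was planted.

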