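# brainphen

Multimodal brain-health phenotyping for aging cohorts: weighted
functional-connectivity networks, small-world propensity, covariate-free
feature preparation, hierarchical phenotype discovery, and nutrient
biomarker profiling — with a synthetic cohort generator so the whole
analysis is testable end to end.

## The problem

Chronological age is a poor summary of brain health in late life: two
70-year-olds can differ widely in cortical volume, white-matter integrity,
functional network organization and metabolite concentrations. `brainphen`
is for researchers who want to classify elderly participants into
*accelerated* versus *delayed* brain-aging phenotypes from a multimodal
feature table — regional gray-matter volumes, DTI fractional anisotropy,
MRS metabolites and graph-theoretic functional connectivity — and then ask
what distinguishes the phenotypes: predicted brain age, cognitive
performance, and blood nutrient biomarkers.

## The method

**Connectivity.** For each participant, pairwise Pearson correlations
between node BOLD time series are Fisher-transformed and standardized,
Z = arctanh(r)·√(n−3) (n time points), thresholded at a one-sided
Bonferroni-corrected level over all p(p−1)/2 node pairs (only significant
positive correlations are kept), and the surviving Z-scores rescaled to
connection weights in [0, 1]. Subnetworks of seven intrinsic connectivity
networks are extracted from the whole-brain thresholded matrix.

**Small-world propensity.** For a weighted network with clustering
coefficient C_obs and characteristic path length L_obs, and degree-matched
lattice and random null networks,

    phi = 1 − sqrt((Delta_C^2 + Delta_L^2) / 2)
    Delta_C = (C_latt − C_obs) / (C_latt − C_rand)
    Delta_L = (L_obs − L_rand) / (L_latt − L_rand)

with both deviations clipped to [0, 1]. Clustering is the Onnela
geometric-mean triangle intensity; path lengths use edge length 1/weight;
the lattice null places the weight multiset band-by-band near the
diagonal; the random null is degree-preserving Maslov–Sneppen rewiring
with reshuffled weights. A ring lattice scores phi ≈ 1 − √½ ≈ 0.293
(Delta_C = 0, Delta_L = 1), a dense random graph mirrors it, and a
Watts–Strogatz network scores well above both.

**Phenotyping.** Every feature is residualized against age, sex,
education, income and BMI (Frisch–Waugh–Lovell partialling), normalized
with Tukey's Ladder of Powers (lambda chosen on a grid to maximize
Shapiro–Wilk W; monotone, rank-preserving), and min-max scaled to [0, 1].
Participants are clustered on the prepared *brain* features only
(complete-linkage, Euclidean), the tree is cut into two groups, and the
cluster with better structural integrity is labeled *delayed*. Phenotypes
are then compared on every feature by Welch t-tests, on brain age (group
means, gap, modality correlations), and the significantly delayed-higher
nutrients form the nutrient profile.

## Worked example

```r
library(brainphen)
g   <- generate_cohort(cohort_config(seed = 1))   # 100 synthetic elders
fit <- brain_phenotypes(g$cohort)
fit
#> Brain-health phenotypes (complete-linkage, two-group cut)
#>   accelerated: 49   delayed: 51   mean silhouette: 0.129 (null q95 0.028)
#>   brain age: accelerated 64.7 vs delayed 58.2 yr (gap 6.5, t = 3.22, p = 0.00176)
#>   154/181 features differ at alpha = 0.05; 12 nutrients in the delayed profile
```

The cohort generator plants two latent phenotypes; the fit recovers them
(adjusted Rand index vs. the planted labels ≈ 0.96 at this seed), the
delayed group shows a younger mean brain age, and 12 of the 13 planted
nutrient effects surface in the delayed-phenotype profile. `summary(fit)`
prints the per-domain group means, brain-age modality correlations and the
nutrient table; `plot(fit)` draws the dendrogram colored by phenotype.

The small-world propensity machinery is exposed directly:

```r
s <- small_world_propensity(ring_lattice(30, 4), seed = 1)
s
#> Small-world propensity: phi = 0.2929 (Delta_C = 0.000, Delta_L = 1.000)
#>   C: obs 0.5000 | lattice 0.5000 | random 0.0800
#>   L: obs 4.1379 | lattice 4.1379 | random 2.4949  (10 null reps)
```

A fully reproducible run (artifacts + md5 manifest + resolved YAML config)
is one call: `run_pipeline(run_config(output_dir = "run1", seed = 7))`.

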