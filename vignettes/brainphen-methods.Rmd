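---
title: "Methods: multimodal brain-health phenotyping with brainphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal brain-health phenotyping with brainphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainphen)
```

`brainphen` classifies elderly participants into *accelerated* and
*delayed* brain-aging phenotypes from a multimodal feature table and asks
what distinguishes the two groups. This vignette documents the model, the
parameter choices and their rationale, the synthetic cohort the package
validates itself on, and the numerical decisions a maintainer should know
about.

## 1. Connectivity construction

A participant's node-by-time BOLD panel becomes a weighted graph in four
steps.

1. **Pearson correlations** between all node pairs. Zero-variance nodes
   are rejected by name rather than producing `NaN` rows.
2. **Fisher-Z standardization**: `Z = arctanh(r) * sqrt(n - 3)`, where `n`
   is the number of time points. Under the null of zero correlation the
   off-diagonal entries are approximately standard normal, which is what
   makes a Z threshold meaningful. `n <= 3` is rejected because the
   approximate standard deviation `1/sqrt(n - 3)` is undefined. We
   *divide* by this standard deviation — the standard variance
   stabilization; multiplying by it (which one sometimes sees written)
   would shrink the transform rather than standardize it.
3. **Bonferroni threshold**, one-sided: entries survive only if
   `Z > qnorm(1 - alpha/m)` with `m = p(p-1)/2` unique pairs by default
   (19,900 for the default 200-node parcellation). Only significant
   *positive* correlations are kept; negative correlations are discarded
   by construction.
4. **Rescaling to [0, 1]**: retained Z-scores are divided by the
   within-matrix maximum, so the strongest connection gets weight 1 and
   zeros are preserved exactly. A min–max dialect over the retained edges
   is available (`rescale = "minmax"`); it maps the weakest retained edge
   to a small positive value instead of preserving relative magnitudes.
   A matrix with no surviving edges is returned flagged (`attr "empty"`),
   never as silent zeros.

Subnetworks (seven intrinsic connectivity networks) are **extracted after
thresholding** the whole-brain matrix, not re-thresholded per network:
edge significance is a whole-brain statement, and re-thresholding small
subnetworks would change `m` and hence the retained graph per network.

## 2. Graph metrics and small-world propensity

For a weighted adjacency `W` (symmetric, zero diagonal, weights in
[0, 1]):

* **Clustering** is the Onnela geometric-mean triangle intensity with
  weights normalized by the matrix maximum; nodes of binary degree < 2
  contribute 0. This is the convention of the small-world-propensity
  literature; the choice matters because the deviation `Delta_C` below
  compares observed and null clustering on the same scale.
* **Path length** uses edge length `1/w` (configurable to `-log(w)`), and
  the characteristic path length is the mean over ordered *reachable*
  pairs. Bonferroni-thresholded graphs can fragment, so unreachable pairs
  are excluded and flagged rather than failing.
* **Global efficiency** is the mean of `1/d(i,j)` over ordered pairs
  (unreachable contributes 0); **local efficiency** averages the global
  efficiency of each node's neighborhood subgraph; **strength** is the
  mean of summed incident weights.

Small-world propensity is

$$\phi = 1 - \sqrt{\frac{\Delta_C^2 + \Delta_L^2}{2}}, \qquad
\Delta_C = \frac{C_{latt} - C_{obs}}{C_{latt} - C_{rand}}, \qquad
\Delta_L = \frac{L_{obs} - L_{rand}}{L_{latt} - L_{rand}},$$

with both deviations clipped to `[0, 1]` so that a network *more*
clustered than its lattice null, or *shorter-pathed* than its random null,
cannot push `phi` outside `[0, 1]`. If a null spread degenerates
(`C_latt ≈ C_rand`) the deviation is defined as 0 and flagged.

**Null models.** The random null performs Maslov–Sneppen edge swaps on
the binary structure — every node's degree is preserved exactly — and then
reshuffles the weight multiset uniformly over the rewired edges. The
lattice null places the same number of edges with the identical weight
multiset band-by-band at increasing circular distance from the diagonal,
largest weights nearest; a ring lattice with uniform weights is a fixed
point of this construction. The lattice construction preserves the degree
sequence only approximately (it is a best-effort placement, flagged when
degrees change), which is the standard behavior of lattice nulls for
arbitrary degree sequences. Null `C`/`L` values are averaged over
`n_null = 10` seeded replicates by default — the lattice is deterministic,
so the averaging matters only for the random null; 10 replicates keep the
Monte-Carlo error of `C_rand`/`L_rand` well below the clipping tolerance
on graphs of a few hundred nodes.

These choices yield the two analytic fixed points used in the tests: a
ring lattice gives `Delta_C ≈ 0, Delta_L ≈ 1`, a dense random graph the
mirror image, both with `phi ≈ 1 - sqrt(1/2) ≈ 0.293`, and Watts–Strogatz
graphs at rewiring probability ~0.1 score well above both.

## 3. Feature preparation

Each feature column (brain, cognition and nutrients alike) passes through:

1. **Frisch–Waugh–Lovell residualization** against age, sex, education,
   income and BMI (sex and any other factor as indicator columns). The
   residuals equal direct least-squares residuals of the outcome on
   `[1, X]` and are orthogonal to every covariate; rank-deficient
   covariate matrices are rejected naming the collinear columns. The
   covariate list is configurable — the five defaults are the standard
   confounders of age-related cognitive decline.
2. **Tukey Ladder of Powers**: residuals are shifted to strictly positive
   support (minimum subtracted, plus an offset of 1e-6 of the range — the
   ladder needs positive support and residuals are signed), then
   `x^lambda` (`lambda > 0`), `log x` (`lambda = 0`) or `-(x^lambda)`
   (`lambda < 0`) is applied with `lambda` chosen on the grid −2…2 in
   steps of 0.025 to maximize the Shapiro–Wilk W statistic. Every branch
   is monotone increasing, so ranks are preserved exactly; ties in W
   resolve toward `lambda = 1`.
3. **Min–max scaling** to `[0, 1]`. Constant columns are rejected at
   every stage (including columns that become constant after
   residualization), never silently imputed.

The chosen `lambda`, positivity shift, scaling bounds and projection
coefficients are recorded per column, so the preparation is replayable on
new data (`predict()` uses exactly this replay).

## 4. Phenotype discovery and comparison

Participants are clustered with **complete-linkage** hierarchical
clustering on **Euclidean** distances between prepared rows, restricted to
the brain domains (structure, metabolism, connectivity). Cognition and
nutrients are deliberately excluded from the distance: they are the
outcomes later tested between phenotypes, and including them would leak
the result into the grouping. The tree is cut at `k = 2` (the final merge
removed) — two phenotypes is the scientific hypothesis, not an inference
from the dendrogram. Complete linkage guarantees monotone merge heights,
which the tests assert on every tree.

The two clusters are **oriented** by structural integrity: the cluster
with the higher mean over the prepared volumetric and DTI columns is
labeled *delayed*. Exact ties (possible only on degenerate data) break
deterministically by cluster size, then smallest participant id, and the
applied rule is recorded on the assignment.

**Separation.** A two-group cut always exists, even on pure noise, so the
fit carries a calibrated flag: the mean silhouette width of the cut is
compared with the 95th percentile of its null distribution, obtained by
clustering 20 column-wise permutations of the same prepared matrix
(shuffling each column independently preserves every marginal but
destroys joint cluster structure). Fixed silhouette rules of thumb
(e.g. 0.25) are dimension-naive: with ~137 weakly informative columns a
cohort recovered at ARI ≈ 0.96 has mean silhouette only ≈ 0.13, while its
permutation null sits near 0.03.

**Comparison.** Per-feature **Welch** t-tests by default — the
unequal-variance test is the safer default when group variances are not
known to match; the pooled variant is a switch. P-values are reported
unadjusted at `alpha = 0.05` (comparisons are descriptive of the
phenotype contrast), with a Benjamini–Hochberg adjusted column always
emitted alongside. The brain-age report gives group means in years, the
exact mean difference, its t-test, and Pearson correlations between brain
age and per-domain composites. Composites are unweighted means of the
prepared columns, with one refinement: connectivity columns whose manifest
`direction` is −1 (network strength and efficiencies, which empirically
run *opposite* to brain health) enter reflected as `1 − x`. A naive
unweighted mean over a connectivity domain dominated by such inverse
measures would correlate *positively* with brain age even when better
connectivity tracks a younger brain; orienting by the declared direction
flag — the same mechanism that handles reverse-scored cognitive tests —
keeps every composite pointing toward better brain health. The nutrient
profile is the set of nutrient features significant at `alpha` with a
higher delayed than accelerated mean (direction matters: a significant
accelerated-higher nutrient is not part of a delayed profile).

## 5. The synthetic cohort

Because real multimodal cohorts of this kind are available only on
request, the package ships a generator that plants known structure:

* 100 participants, half per phenotype; 68 volumetric + 34 DTI + 3 MRS +
  32 connectivity features (4 graph metrics × 7 networks + whole brain);
  15 cognitive scores with two reverse-scored (reaction time and error
  counts, generated with negated effect direction); 29 blood nutrients of
  which 13 carry a planted effect of d = 0.8 and 16 are null; covariates
  drawn independently of phenotype so they cannot explain the grouping.
* Every feature is Gaussian with within-group SD 1 and a group-mean shift
  equal to its planted standardized difference. Gaussian noise is a
  deliberate simplification: the pipeline Tukey-transforms toward
  normality anyway, and analytic noise keeps the recovery tests exact.
* Per-domain planted effects default to volume 0.8, DTI 1.0, metabolism
  0.4, connectivity 0.8 — ordered like the relative group gaps of the
  motivating study (DTI largest, metabolites by far smallest), chosen
  once at design time. Network-level strength and local/global efficiency
  are planted with *reversed* sign (accelerated higher), matching the
  empirical pattern that these metrics run opposite to the other health
  measures; small-world propensity and the whole-brain slots favor the
  delayed group.
* Brain age: group means 65.1 and 59.7 years with SD 10 — the SD is
  back-solved so that a 5.4-year gap at n = 100 carries a t-statistic
  near 2.7, matching the effect size scale reported for real cohorts.
  Cognition uses d = 0.4: large enough that the delayed group wins on
  average everywhere, small enough that only a subset of the 15 tests
  reaches significance in any one cohort, as observed in practice.
* BOLD panels: 210 time points (7 minutes at TR = 2 s) over a 200-node
  parcellation. The target correlation places 0.5 on the edges of a
  Watts–Strogatz graph whose nodes are ordered so each network occupies a
  contiguous ring block (making most lattice edges within-network), and
  the nearest valid correlation matrix is obtained by eigenvalue clipping
  before Cholesky sampling. Delayed participants get rewiring probability
  0.1 (strongly small-world), accelerated 0.9 (near-random), so the
  measured-connectivity route reproduces the small-world-propensity
  contrast. Edge correlation 0.5 is a typical magnitude for functionally
  connected cortical regions and comfortably exceeds the Bonferroni
  retention threshold (~0.31 at these sizes), so the planted topology
  survives thresholding.

What the generator does **not** emulate: spatial autocorrelation and
hemodynamics of real BOLD, heavy-tailed or skewed assay distributions,
missing data, site/batch effects, and correlated feature blocks within a
modality (features are independent given the phenotype). Passing tests
therefore demonstrate that the machinery is correct and calibrated under
planted truth — not that real cohorts will separate this cleanly.

## 6. The end-to-end run

`run_pipeline()` executes simulate → (optionally measured connectivity →
graph metrics) → prepare → cluster/orient → compare, writing every
artifact as delimited text plus a md5 manifest and the resolved YAML
config; identical config and seed give identical hashes (the config is
written with its output directory relativized so the hash does not depend
on where the run lives). One master seed fans out to per-stage seeds by a
counter-based derivation, keeping each stage independently reproducible.

By default the phenotype table uses the generator's planted Gaussian
connectivity features; `timeseries = TRUE` switches to the measured route
(simulate BOLD panels, build thresholded connectivity, compute the 32
graph-metric features and substitute them into the cohort). The default
keeps the standard run fast and makes the planted direction pattern exact
by construction; the measured route exercises the full graph pipeline and
is validated separately. On the measured route, very small subnetworks can
fragment below the edge threshold; affected feature columns are left at
their simulated values and reported in a warning rather than aborting the
run.

## 7. Numerical choices and test scales

* Tolerances: graph metrics match Floyd–Warshall and exhaustive-triangle
  oracles to 1e-9; FWL residuals match normal-equations solutions to
  1e-8; the `phi` identity holds to machine precision from the stored
  deviations.
* Test problem sizes are chosen for tight oracles at interactive speed:
  brute-force graph checks use ≤ 12 nodes (200 random graphs), SWP fixed
  points use the canonical ring lattice (n = 30, k = 4), dense random
  (n = 30, p = 0.9) and Watts–Strogatz (n = 100, k = 10, beta = 0.1)
  configurations, recovery and power simulations use 20 seeded cohorts of
  n = 100, and t-test calibration uses 10,000 null replicates.
* Degenerate inputs have defined behavior throughout: empty graphs are
  flagged, not zeroed silently; constant columns are rejected by name;
  degenerate null spreads define the deviation as 0 with a flag; exact
  orientation ties break deterministically and record the rule.

## 8. Known limitations

* The lattice null's approximate degree preservation means `Delta_C` can
  be slightly conservative on graphs with highly heterogeneous degrees.
* `k = 2` is imposed, not selected; no cluster-stability bootstrap or gap
  statistic is included.
* No missing-data handling beyond rejection; no imputation, robust
  regression or batch correction.
* The Shapiro–Wilk criterion for the Tukey ladder is computed on at most
  5000 points (the statistic's implementation limit); cohorts of this
  scale are far below it.
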