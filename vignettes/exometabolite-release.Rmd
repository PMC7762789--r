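---
title: "Classifying released exometabolites over stationary phase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying released exometabolites over stationary phase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomet)
library(dplyr)
```

## The problem

Bacteria at carrying capacity are not metabolically silent: they keep
transforming their environment by releasing small molecules — exometabolites —
through transport or, less interestingly, through lysis. Untargeted LC-MS of
spent medium over a stationary-phase time course produces thousands of aligned
features (an m/z–retention-time pair quantified by peak area per sample), most
of which are medium components, contaminants, or noise. The scientific object
of interest is the subset of features that *accumulate* over stationary phase
above the sterile-medium background: the **released exometabolites**.

`exomet` implements that definition as a reproducible classifier, together
with the surrounding pipeline: internal-standard normalization, longitudinal
composition statistics, cross-strain partitioning of the released set, and a
transcriptome-side classification of transporter genes that supports the
release-from-intact-cells interpretation.

The package assumes the monoculture time-course design it was written for:
several strains, an exponential-phase time point (12.5 h by default) followed
by stationary-phase time points (25–45 h every 5 h), up to 4 destructively
sampled replicates per time point, medium-only *external controls*, extraction
blanks, and spiked internal standards (ITSDs), acquired separately per
polarity/ionization mode.

## The six release criteria

For one strain and one mode, a feature is **released** iff it passes all six
criteria. Writing $x_{t,r}$ for the peak area at time $t$, replicate $r$,
$m_t$ for the replicate mean, and $C$ for the set of external-control peak
areas across the whole time series:

1. **Control maximum** — the global maximum over strain and control samples
   must not lie in a control replicate. Ties between a strain sample and a
   control at the maximum fail (conservative).
2. **Noise ratio** — $\min_r x_{45,r} \ge 3 \cdot \max C$, and the 45-h
   minimum must be positive. The factor 3 separates genuine signal from the
   medium background.
3. **Replicate CV** — at every time point with $\ge 2$ replicates, the
   coefficient of variation $100\,s_t/m_t$ (with the $n-1$ standard
   deviation) must be below 20%. $s_t = 0$ defines CV $= 0$: a reproducibly
   constant — including reproducibly absent — signal is reproducible.
   Single-replicate time points are skipped, not failed.
4. **Minimum at the first time point** — $m_{12.5} \le m_t$ for every $t$,
   non-strict: a tie with a later time point still passes.
5. **Fold change** — $\log_2(m_{45}/m_{12.5}) > 1$, strictly. A zero
   baseline with positive 45-h signal gives $+\infty$ and passes; a feature
   absent at both ends fails.
6. **Correlation with time** — the Pearson correlation of abundance against
   time (hours) must be $\ge 0.7$. A constant abundance has an undefined
   correlation and fails.

All six criteria are evaluated for every feature (no short-circuiting), so
the report from `classify_released()` doubles as a per-criterion diagnostic.
Criteria are scale-free: multiplying every peak area of the strain and its
controls by any $c > 0$ changes no verdict.

Three conventions deserve emphasis because the verbal definition leaves them
open; each is fixed once and covered by tests:

* **CV uses the $n-1$ standard deviation** (the sample estimator a
  statistician would default to for 2–4 replicates).
* **The correlation is computed on replicate-level (time, abundance) pairs**
  by default, using all data rather than six means; the time-point-mean
  variant is exposed via `pearson = "means"`.
* **The control pool is every external-control sample of the mode across the
  whole time series**, not a time-matched subset; the control is
  medium-only, so pooling only tightens the background estimate.

Criteria 1 and 2 are logically nested: if the global maximum sits in a
control, the 45-h minimum cannot be three times the control maximum. The
classifier still reports them separately because criterion 1 can fail alone
only in degenerate all-zero cases, and because the separate verdicts make the
diagnostics interpretable.

## Normalization

Heat maps and ordination work on normalized data. `select_reference_itsd()`
picks, per table (hence per mode), the spiked internal standard with the
lowest percent CV across all samples — candidates with a zero value in any
sample are excluded, and ties break lexicographically.
`normalize_features()` divides every feature by the reference ITSD in the
same sample and takes the cube root:

$$v_{fs} = \left(\frac{a_{fs}}{a_{\mathrm{ref},s}}\right)^{1/3}.$$

Division by a per-sample reference cancels injection-volume and instrument
drift effects exactly (any per-sample multiplicative factor divides out);
the cube root compresses the dynamic range while preserving within-sample
rank order. `zscore_features()` centers and scales each feature (again with
the $n-1$ standard deviation) for Euclidean-distance heat maps; constant rows
map to zeros so planted or degenerate features cannot produce NaNs.

## Longitudinal composition statistics

Between-sample dissimilarity uses **Bray-Curtis** on normalized profiles,
$BC(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, with two all-zero
profiles defined as distance 0. **PCoA** (`pcoa_ord()`) is classical metric
scaling: Gower double-centering of $-\tfrac12 D^2$ and an
eigendecomposition. Coordinates are reported on positive-eigenvalue axes
scaled by $\sqrt{\lambda}$; negative eigenvalues (Bray-Curtis is a
semi-metric) are reported unaltered, with no Lingoes or Cailliez correction,
so the user can see the metric distortion rather than have it hidden.

**PERMANOVA** (`permanova()`, backed by vegan's `adonis2`) partitions the
distance matrix with sequential (Type I) sums of squares in the order
`strain`, `time`, `strain:time` — the order the model is written in, fixed
and documented because the sums are order-dependent in unbalanced designs.
P values use the add-one estimator
$p = (\#\{F^* \ge F\} + 1)/(n_{perm}+1)$ over a permutation set the package
builds itself: seeded random permutations (default $n_{perm} = 999$), the
complete enumeration when `exact = TRUE` (so small instances have exact,
assertable p values), or block-restricted permutations. The
repeated-measures variant (`rm_permanova()`) treats each replicate time
series as a block and shuffles time labels only within series — one
defensible reading of a repeated-measures permutation scheme, chosen and
documented rather than inferred. `pairwise_permanova()` runs all group pairs
and applies Benjamini-Hochberg across the pair family.

**Protest** (`protest_comparison()`) measures concordance of two
ordinations (typically the first two PCoA axes of independent replicate
series) by symmetric Procrustes superposition; the statistic $m^2_{12}$ is
the scaled residual after optimal translation, rotation and scaling, and
$\sqrt{1 - m^2_{12}}$ is the Procrustes correlation.

**Centroid dissimilarities** (`centroid_dissimilarity()`) are computed in
normalized-profile space — centroid first, Bray-Curtis between centroids
second — against a baseline time point or stepwise between consecutive time
points. Computing centroids in PCoA space instead would entangle the result
with the axis truncation, so profile space is the default and only mode.
On saturating (decelerating) accumulation trajectories these two views give
the signature longitudinal pattern: distance from the exponential-phase
baseline grows monotonically while successive steps shrink.

`feature_anova()` closes the loop at the single-feature level: one-way ANOVA
across strains at the last time point with BH adjustment across features.
Degenerate features are resolved by convention (no between-group variation:
$F = 0$, $p = 1$; perfect separation with zero residual: $F = \infty$,
$p = 0$).

## The synthetic study design

`simulate_feature_table()` generates the whole design with known ground
truth, so every stage is testable without raw instrument data. Released
features follow

$$\mu(t) = a \cdot 2^{\,k\,(t - t_0)/(t_{\mathrm{last}} - t_0)}, \qquad
k \in [1.5, 3],\ a \in [2000, 8000],$$

which guarantees LFC $= k > 1$, a mean minimum at $t_0$, and a strong
positive correlation with time. Replicate noise is multiplicative lognormal
parameterized by its CV (peak areas are nonnegative and heteroscedastic;
multiplicative noise preserves the CV target across magnitudes, and the
log-scale mean is shifted by $-\sigma^2/2$ so the arithmetic mean is exact).
Controls sit at a configurable background level (200 by default, an order of
magnitude below the planted trajectories, so the 3x noise margin is
realistic rather than trivial); internal standards are near-constant at 2%
CV, the reproducibility a spiked standard should show.

One decoy family per criterion violates exactly its own rule at zero noise:
a control-sample spike at twice the global maximum (D1); a trajectory ending
at only twice the control maximum (D2); one time point with its replicate
spread inflated to 40% CV by deterministic multipliers (D3); a trajectory
dip to half the baseline at 30 h (D4); an exponent giving LFC $= 0.5$ (D5);
and a rise-then-fall trajectory whose correlation with time falls below 0.7
(D6). D1 is the one exception to orthogonality: failing the control-maximum
rule *implies* failing the noise rule (see above), so D1 fails criteria 1
and 2 and passes 3–6 — the mathematically attainable version of the
one-criterion-per-decoy design. Configurations that make decoys
unconstructable (replicate CV at or above the 20% threshold, too few
replicates for the spread decoy, too few time points for the trajectory
decoys) are rejected up front as infeasible.

The generator does **not** emulate chemically meaningful m/z or retention
time values, chromatographic peak shapes, retention drift, batch effects, or
correlated noise between features. Passing tests therefore demonstrate that
the pipeline's logic is correct under the stated noise model — not that the
noise model captures everything real instruments do. Whole-sample dropout
(failed injections) is available via `dropout`, capped at one sample per
strain/time-point group so grouped statistics stay computable.

`simulate_count_table()` generates the transcriptome side: negative-binomial
counts (deterministic rounded means at zero noise) over two well-separated
mean blocks — a low-expression block (25% of genes by default, means 12–30,
chosen to survive the count filters yet sit below the quartile threshold)
and an expressed block (means 200–2000) — plus a fabricated DE table and a
transporter list with planted nested classes.

## Transcript thresholds

`filter_genes()` applies the two count-matrix rules in order: all-zero genes
out, then genes with counts $\le 10$ in strictly more than 90% of samples
out. `compute_lem()` summarises each gene by its mean count and takes the
25th percentile (R's default linear-interpolation quantile) of those
summaries as the low-expression minimum; a gene is expressed iff its mean is
strictly above it. The underlying cumulative-abundance construction can be
read several ways (quantile over genes, over reads, or over the curve); the
per-gene-mean reading is implemented because it is the simplest rule that is
monotone in expression, and it is stated precisely so results are
reproducible. Reproducing a specific study's threshold values would require
that study's data and its exact rule. `classify_transporters()` then counts
the nested classes — above the minimum; additionally differentially
expressed ($Q < 0.01$, strict); additionally any stationary-phase
$\mathrm{LFC} > 1$, strict — consuming an externally produced DE table: the
negative-binomial DE model itself is deliberately out of scope.

## Worked example

```{r pipeline}
cfg <- sim_config(seed = 42)
sim <- simulate_feature_table(cfg)

report <- classify_released(sim$features, sim$meta, strain = "S1")
count(report, released)

ref <- select_reference_itsd(sim$features, sim$itsd_ids)
norm <- normalize_features(sim$features, ref)

keep <- sim$meta$class %in% cfg$strains
ids <- sim$meta$sample_id[keep]
d <- bray_curtis(as_profile_matrix(norm)[ids, ])
fit <- permanova(d, sim$meta[keep, ], ~ class * time_h, n_perm = 199, seed = 1)
tidy(fit)
```

With planted strain-specific feature sets, strain explains most of the
variation and the interaction term is large — the structure the design is
built to detect. The per-strain released sets partition across strains:

```{r partition}
sets <- lapply(setNames(cfg$strains, cfg$strains), function(s) {
  released_ids(classify_released(sim$features, sim$meta, s))
})
vp <- venn_partition(sets)
vp$regions
```

## Numerical choices and test problem sizes

* Percentages are rounded half up to one decimal (`18.57` to `18.6`),
  matching how such summaries are conventionally printed.
* The shared-feature percentage uses the sum of per-strain unique counts as
  its denominator; the computation is documented by its formula in
  `shared_fraction()` rather than by intent.
* Permutation p values are never reported as 0: the add-one estimator has a
  floor of $1/(n_{perm}+1)$.
* Exact enumeration is capped at 40320 permutations (8!) to bound memory and
  time; larger instances use seeded random sets.
* The test suite runs the full synthetic design at its defaults (about 300
  features, 120 samples per table, 800 genes) and exercises the
  classifier-against-oracle comparison over 20 seeds of a reduced design —
  about 1300 features checked criterion by criterion — keeping the whole
  suite under half a minute on one CPU.

## Limitations

* The pipeline starts from an aligned feature table; peak picking,
  alignment, and integration (e.g. MZmine) are upstream and out of scope, as
  are spectral-library matching and ontology prediction — identification
  enters only as an annotation table of MSI levels.
* The release definition is deliberately conservative: features that
  accumulate late but fail the monotone-minimum or correlation criteria are
  excluded, and with 2 replicates the CV criterion has limited power, so
  real released counts are best read as lower bounds.
* Blank subtraction, drift correction and imputation are intentionally
  absent — the pipeline's definition of signal is relative to measured
  external controls, not to modelled backgrounds.
* The repeated-measures permutation scheme and the low-expression-minimum
  quantile rule are each one defensible formalisation of a loosely specified
  procedure; both are documented above and fixed by tests.
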