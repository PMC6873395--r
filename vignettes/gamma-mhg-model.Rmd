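---
title: "The gamma-MHG model behind mhgsim: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gamma-MHG model behind mhgsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhgsim)
```

## The generative model and its assumptions

`mhgsim` generates a 16S amplicon count table in two stochastic stages per
sample.

**Biological stage.** For feature $i$ in group $k$, the abundance of that
feature in a biological replicate is
$m_{ij} \sim \Gamma(\text{shape} = 1/\phi_{ik},\ \text{scale} = \phi_{ik}\mu_{ik})$,
so $\mathbb E[m_{ij}] = \mu_{ik}$ and
$\mathrm{Var}(m_{ij}) = \phi_{ik}\mu_{ik}^2$: $\phi$ is the squared
coefficient of variation across replicates. Mixing a Poisson sampling stage
over a gamma-distributed rate is exactly the construction that yields
negative-binomial marginals with variance $\lambda(1 + \lambda\phi)$, so
$\phi$ plays the role of the familiar NB dispersion. Two degenerate limits
are first-class inputs, not errors: $\phi = 0$ gives a deterministic
abundance (technical-replicate regime) and $\mu = 0$ a structurally absent
feature.

**Sequencing stage.** The continuous abundances are converted to an integer
pool of amplified fragments $\mathbf m_j$ (see "population construction"
below) and the library size $n_j$ is drawn from the pool *without
replacement*:
$\mathbf Y_j \sim \mathrm{MHG}(n_j, \mathbf m_j)$.
This encodes two physical facts. First, a read consumes a fragment, so
selection probabilities drift during the run — the multinomial
(with-replacement) model is only the limit for a vanishing sampling
fraction, and how quickly that limit is reached depends strongly on how
skewed the composition is. Second, the sequencer's capacity is a hard
total, which makes the counts compositional: a feature can only gain reads
at the expense of the others. Zeros need no extra mixture component:
$P(Y_{ij} = 0) = \binom{M_j - m_{ij}}{n_j}\big/\binom{M_j}{n_j}$ rises
steeply as $m_{ij}$ falls, so rare features drop out at exactly the rate
the urn dictates (`zero_probability()` exposes the closed form, evaluated
in log space).

Assumptions worth stating: features are independent at the parameter level
(dependence arises only through the shared pool and fixed capacity);
library sizes are fixed per-sample constants supplied by the user, not
random; and no read-level artifacts (chimeras, PCR bias, taxonomy error)
are modelled — the output is a count table, not reads.

The declared ground truth of a run is the relative-abundance matrix
$m_{ij}/\sum_i m_{ij}$ recorded after the gamma stage and before
sequencing; it is what normalization, imputation or differential-abundance
methods should be benchmarked against.

## Population construction (a documented gap)

The MHG needs an integer urn, but the gamma stage is continuous, and the
conversion rule is not dictated by the model. `build_population()`
apportions the continuous abundances by largest remainder onto a target
total $\max(\mathrm{round}(\sum_i \text{raw}_i),\ \lceil n_j \cdot
\text{population\_scale}\rceil)$. Largest remainder hits the target total
exactly, is the proportion-error-minimizing rounding, and provably never
assigns fragments to a feature with zero raw abundance (the number of
leftover units is strictly smaller than the number of positive fractional
parts), so structural zeros survive the conversion. `population_scale`
(default 1) is exposed because no canonical conversion rule exists for this
model family: raising it enlarges the pool relative to the
depth, pushing the sequencing stage toward the multinomial regime.

## MHG sampling algorithm

`sample_mhg()` uses the exact sequential decomposition: conditional on the
draws consumed by features $1..i-1$, feature $i$ is univariate
hypergeometric with the remaining pool and remaining draws, and the last
feature takes the remainder. This is exact (not an approximation or a
rejection scheme), $O(C)$ per sample, and conserves the column total by
construction. The joint law is invariant to the feature order used in the
decomposition; the implementation fixes the input order, so output is
seed-dependent but distributionally order-free (checked empirically in the
suite). Two shortcuts avoid degenerate `rhyper` calls: zero remaining
draws stops early, and remaining draws equal to the remaining pool takes
everything.

## Parameters that matter

| parameter | meaning | unit/scale | default | why |
|---|---|---|---|---|
| `mu` | mean feature abundance per group | arbitrary (only proportions reach the counts) | — | user/estimated |
| `phi` | biological variability | squared CV, dimensionless | — | user/estimated |
| `lib_sizes` | reads per sample | counts | — | user/estimated (raw column sums) |
| `population_scale` | min pool size as multiple of depth | dimensionless ≥ 1 | 1 | no canonical rule; 1 is the least-assumption feasible pool |
| `phi_floor` | lower clip for estimated `phi` | dimensionless | 1e-8 | corrected moment estimator can go negative at low variance |
| `min_replicates_for_phi` | replicates needed to estimate `phi` | count | 2 | variance undefined below |
| `n_boot`, `boot_fraction`, `alpha` | bootstrap protocol | — | 10000, 5%, 0.05 | standard sizes for feature-subset bootstraps at this scale |

## Estimation choices

Only relative abundances are recoverable from a count table, so estimated
`mu` lives on the normalized count scale; this is sufficient because the
simulator renormalizes into the pool anyway. Normalization is total-sum
scaling to the mean library size (self-contained, deterministic,
count-scale), with DESeq-style median-of-ratios as an alternative; external
single-cell normalization tools are deliberately not a dependency. The default dispersion estimator subtracts
the Poisson sampling component before normalizing by $\hat\mu^2$
($\hat\phi = (s^2 - \hat\mu)/\hat\mu^2$, clipped at `phi_floor`), because
the naive $CV^2 = s^2/\hat\mu^2$ conflates technical and biological
variance and overestimates $\phi$ badly for low-count features; $CV^2$ is
available for comparison and is provably never smaller. Features absent
from a group get $\hat\mu = \hat\phi = 0$ and stay structurally absent in
re-simulation. Groups with a single replicate are a hard error pointing at
hybrid mode (`assemble_params()`), where user vectors override estimated
components group-wise — few-replicate designs are precisely where moment
estimates of $\phi$ degrade.

## Presets and the synthetic stated world

The preset families are parameterized recipes spanning the documented regimes of real 16S studies:
features $3\cdot10^2$–$10^4$, groups 2–40, replicates 2–5, depths
$2.8\cdot10^3$–$8.3\cdot10^5$, overall sparsity 70–97%. Choices made once
and not revisited:

* **`total_intensity` default = 20 × mean depth.** The pool a library is
  sequenced from is much larger than the read budget; a ~5% sampling
  fraction keeps the technical variance component near-Poisson (the regime
  the corrected dispersion estimator assumes) while remaining genuinely
  without-replacement.
* **`fraction_absent_per_group`** (default 0) draws a per-group random
  subset of features with $\mu = 0$. This models community turnover across
  conditions, which — not depth — is the dominant zero source in designs
  with many distinct communities sharing one feature catalogue; abundance
  skew alone cannot produce 97% sparsity at $3\cdot10^5$ reads over 310
  features. The cheese-like preset uses 0.96, the gut-like 0.72.
* **Differential abundance** (`fraction_da_features`, `da_fold_change`)
  multiplies a per-group random feature subset by the fold change, half up
  and half down (odd counts round toward up), so benchmarking workflows
  have a known DA ground truth.
* Skew defaults (log-normal sdlog 2.5–2.8, geometric ratios near 1) were
  fixed against the documented sparsity bands of the three regimes before
  the regime tests were frozen.

What a green test on synthetic data does *not* establish: fidelity to any
particular real dataset (no real table ships with the package), taxonomic
correlation structure between features (parameters are independent), or
robustness to depth heterogeneity beyond what `depth_range` spans.

## Evaluation protocol

`compare_tables()` compares per-feature distributions of within-group mean
intensity and variance between two tables with a two-sided Mann–Whitney U
test. Because feature counts are in the thousands, raw p-values are almost
meaningless; the protocol therefore reports (a) the rank-biserial
correlation $r = 1 - 2U/(n_1 n_2)$ as effect size, with $|r| < 0.1$ read
as negligible (a documented convention of this package, chosen as the
MWU-native effect size), and (b) a bootstrap of 10000 feature subsets of
5% drawn without replacement within an iteration, reporting the fraction
significant at $\alpha = 0.05$. Self-comparison is an exact null
($U = n^2/2 \Rightarrow r = 0$). Sparsity agreement is summarized as
$R^2$ between group sparsities and between percentile grids (1–99) of the
per-feature and per-sample sparsity distributions; $R^2$ is defined as 1
when the two sides agree exactly even with zero spread, and undefined
(`NA`) when one side alone is degenerate. Zero-mean features are excluded
from intensity/variance comparisons only when zero in *both* tables — a
zero/non-zero mismatch is evidence of disagreement and is kept.

## Numerical and reproducibility notes

* One root seed expands into per-sample substreams drawn in a fixed
  (group, sample) enumeration order, so results are bit-identical for the
  same seed and independent of iteration order; preset expansion and the
  bootstrap save and restore the caller's RNG state.
* `zero_probability()` works entirely in `lchoose` space; pool sizes of
  $10^7$ are safe.
* Ties in largest-remainder rounding break toward the earlier feature
  index; ties in the up/down DA split break toward up.
* The MWU p-value uses the tie-corrected normal approximation with
  continuity correction (verified against
  `wilcox.test(exact = FALSE, correct = TRUE)` in the suite); with
  feature-scale sample sizes the exact-permutation p-value is neither
  needed nor affordable inside a 10000-iteration bootstrap.
* Written relative-abundance matrices carry 15 significant digits so
  columns re-sum to 1 within $10^{-9}$ after a round-trip.

## Known limitations

Parameter-level feature independence (no ecological interaction or
phylogenetic correlation); fixed library sizes (depth variability must be
supplied by the user); moment-based dispersion estimation needs
$\gtrsim 5$ replicates to be useful and 50+ to be tight; the evaluation
normalization is the package's own total-sum scaling, which can shift
absolute intensity scales (but affects both tables symmetrically); no
read-level simulation.
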