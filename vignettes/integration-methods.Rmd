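---
title: "Cross-platform integration of expression datasets: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform integration of expression datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacitus)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical choices that a maintainer would otherwise
have to reverse-engineer from the code.

## The pipeline

The unit of data is a dense probes × samples matrix with a `scale` tag
(`linear_count`, `log2_intensity`, `log2_cpm`, `standardized`). Datasets
are imported into a file-backed store (one directory per accession, all
files TSV/JSON and diff-able), selections are extracted by streaming the
stored matrix one probe row at a time, probe ids are mapped to gene ids,
and two or more selections are merged and normalized together. Metadata
merging keeps the union of attributes in first-seen order, renames the
k-th duplicate sample id to `id_k`, and records the source selection in a
`batch` attribute. Matrix merging intersects the gene sets (all four
algorithms need complete rows; rows are ordered as in the first input) and
concatenates columns.

## Integration algorithms

**Mean-centering** (`sims`) subtracts each gene's within-dataset mean. It
removes additive dataset effects, is idempotent, and preserves
within-dataset variances.

**Gene standardization** (`genestd`) maps each within-dataset gene row to
mean 0, sd 1 (sample sd, divisor *n*−1). Rows with sd below 1e−12 are set
to zero rather than divided by noise. Standardization discards per-gene
scale information, which is exactly its point — and also its known risk:
a gene whose between-condition signal differs in magnitude across
datasets is flattened onto the same scale.

**ComBat** (`combat`) is the parametric empirical-Bayes location/scale
model, batch as the only covariate. Per gene, data are standardized with
the sample-size-weighted grand mean and the pooled residual variance about
the batch means; per batch×gene, location γ̂ and scale δ̂² estimates are
shrunk toward a normal (method-of-moments mean/variance across genes) and
inverse-gamma prior (moment estimators a = (2s² + m²)/s², b = (ms² +
m³)/s²) via the standard fixed-point iteration (tolerance 1e−4 on the
maximum relative change, at most 100 iterations; non-convergence proceeds
with the last iterate and a warning). Design choices worth knowing:

- The pooled variance uses the unbiased ANOVA divisor *n*−*B* (not *n*).
  With it, data whose per-batch gene variances equal the pooled variance
  standardize to exactly unit batch variance, so batch-effect-free data is
  an exact fixed point of the correction — a property the test suite
  asserts at 1e−8. The reference implementations divide by *n*; the
  difference is a factor (n−B)/n on the standardized scale that cancels in
  the adjustment except in this fixed-point property.
- The across-gene moment variances are floored at 1e−12, so an exactly
  constant batch effect degenerates to a point-mass prior (full shrinkage
  to it) rather than a division by zero.
- Shrinkage behaviour to expect: the systematic (across-gene) component of
  a batch shift is removed almost entirely, but each gene's *individual*
  corrected batch mean retains a fraction of its sampling noise — with
  batches of 20 and noise sd 0.5 the per-gene mean-absolute residual sits
  near 0.08, which no location-shrinkage method can push below the noise
  floor. Tests therefore measure the injected (signed, across-gene mean)
  shift, which drops by far more than 20×.
- Scale shrinkage does not vanish at rate faster than (a−1)/(n/2): at
  batches of 500 the mean relative gap between δ* and δ̂ bottoms out
  around 1–2% regardless of how heterogeneous the true scale effects are.
  The location estimates are essentially unshrunk (< 1%) at that size.

**XPN** (`xpn`) is pairwise. Genes are clustered (k-means) into K groups
and the combined samples jointly into L groups on the row-standardized
combined data; per platform the block model x_gs = A(α(g), β(s))·b_g +
c_g + σ_g·ε_gs is fitted by alternating least squares with the
identifiability constraints that block rows of A are (cluster-size
weighted) centered — the offset being absorbed into c — and b has RMS 1
with positive sum within each gene cluster. Platform-specific A, b, c and
σ² are replaced by their sample-size-weighted averages (after sign-aligning
b per gene cluster, since the model is invariant to a joint sign flip),
each platform is reconstructed as Ā·b̄ + c̄ + σ̄·ε̂ with ε̂ the platform's own
standardized residual, and the whole procedure is averaged over
`n_repeats` random clusterings. Defaults K = 25, L = 5, 30 repeats follow
the method's customary settings; both cluster counts are clamped to half
the available genes/samples (with a warning) for small inputs, and the
joint sample clustering is retried, then falls back to fewer clusters, if
some cluster is empty in one platform. Identical inputs are an exact fixed
point (the averaged parameters equal each platform's own and the
reconstruction is the exact residual decomposition); a constant platform
shift moves entirely into c and is removed exactly.

**Counts.** Count-scale inputs are converted to log2-CPM with a +0.5
offset before any of the four algorithms (they all assume approximately
Gaussian log-scale data); method `none` concatenates values untouched.

## The moderated t-test

Per gene, the two-sample pooled-variance t is moderated by shrinking s²_g
toward a prior s₀² with prior degrees of freedom d₀, both estimated across
genes by the method of moments on log s²_g (digamma/trigamma inversion,
Newton's method for the trigamma inverse; d₀ capped at 1e6 in the
degenerate equal-variance case, and recoverable as the ordinary pooled t
by forcing d₀ = 0). p-values use d₀ + n − 2 degrees of freedom. On
simulated data the estimates agree with the `limma` oracle to within a few
percent (asserted in the suite), and the null rejection rate at p < 0.05
is calibrated to [0.04, 0.06]. No voom-style precision weights are applied
to counts — log2-CPM plus moderation only — a documented simplification
that costs a little power at very low counts.

## Synthetic data: what it emulates and what it does not

`simulate_microarray` draws per-gene baselines from Normal(7, 1.5) (log2
intensity units), gives `round(frac_de·n_genes)` genes — half up, half
down — a case-group offset of magnitude |Normal(0, 1)| clamped at ≥ 0.5,
and adds Normal(0, 0.5) per-sample noise. `simulate_counts` draws per-gene
means from a log-normal with median 100 (sdlog 1), per-gene NB dispersions
from a Gamma with mean 0.2 (shape 4), and multiplies/divides the case-group
mean by `effect` (default 1.5) for DE genes. Defaults (10,000 and 12,500
genes, 7 vs 7 samples, 10% DE) are the simulation conditions of the
benchmark protocol; where the upstream simulators' "recommended
parameters" are not published the values above are the package's own,
chosen once as typical of desk-scale DE benchmarks, and configurable.

What a green benchmark does **not** establish: the generators have no
correlation structure between genes, no library-size variation beyond NB
sampling, no outlier samples or arrays, no probe-level effects, and the
two pseudo-studies produced by `random_partition` share a single
generating distribution — so integration methods face a pure, constant
batch design, easier than real cross-platform data. The partition is
stratified by condition (both halves keep both conditions, sizes ⌊n/2⌋ /
⌈n/2⌉): an unstratified split can confound condition with batch, in which
case any batch correction also removes signal — the likeliest cause of
anomalously low AUCs for aggressive per-dataset transforms such as gene
standardization under an unlucky split.

## ROC and AUC

Genes are ranked by ascending p-value; the AUC is the Mann–Whitney
concordance (midrank tie convention), asserted equal to exhaustive
pairwise enumeration on small instances. The full-ranking AUC is the
headline number; a threshold-sweep curve at p ∈ {0.001, …, 0.05} is also
returned because published protocols often report that partial sweep —
the two disagree in general, and the reported AUC magnitudes (≈ 0.65–0.8)
are only reachable on the full ranking.

## Numerical and format conventions

Exports write the sample-name header with an empty leading field so all
lines have equal field count; TSV never quotes (a delimiter inside an id
is an error), CSV quotes RFC-style; numbers are written with 15
significant digits, so write→read round-trips are exact to 1e−9 or
better. Missing matrix cells are imputed with row means at import (with a
warning) because the integration algorithms need complete matrices.
Full-text search tokenizes on non-alphanumeric boundaries, lowercases,
and intersects per-token hit sets; there is no stemming, so `search` is
deterministic and language-agnostic but will not match morphological
variants. Store indexes are plain JSON; column positions are 0-based
internally and never user-facing.

## Known limitations

XPN is strictly pairwise (sequential application is a workaround, not
implemented); ComBat supports no covariates beyond batch and no
non-parametric priors; integration does not tolerate missing values;
cross-species mapping and identifier version reconciliation are out of
scope; and the store enforces no multi-user visibility rules — the
`visibility` field is descriptive metadata.
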