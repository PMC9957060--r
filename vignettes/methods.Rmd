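---
title: "NMF-ReliefF feature selection: model, parameters and design notes"
author: "GeneFamSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NMF-ReliefF feature selection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneFamSelect)
```

# Scope and model

GeneFamSelect selects class-informative features from a nonnegative matrix
$V \in \mathbb{R}_{\ge 0}^{m \times n}$ (features × samples, $m \gg n$)
with a class label per sample. The central selector couples two classical
components:

**Nonnegative matrix factorization.** $V \approx WH$ with
$W \in \mathbb{R}_{\ge 0}^{m \times r}$, $H \in \mathbb{R}_{\ge 0}^{r \times n}$,
fitted by minimizing $\|V - WH\|_F^2$ with the multiplicative updates

$$W \leftarrow W \odot \frac{V H^\top}{W H H^\top}, \qquad
  H \leftarrow H \odot \frac{W^\top V}{W^\top W H},$$

which keep both factors nonnegative and never increase the objective. The
additive, parts-based decomposition is the modelling assumption: a sample's
feature vector is a nonnegative combination of $r$ metagenes (columns of
$W$), which suits count-like data (gene-family copy numbers) and intensity
data, and is exactly why negative input entries are rejected rather than
silently clipped.

**ReliefF.** Each metagene encoding (row of $H$) is scored by ReliefF: for
every sample, the $k$ nearest same-class neighbours (hits) and, per other
class $c$, the $k$ nearest members of $c$ (misses) update each feature's
weight by the prior-weighted miss-minus-hit mean difference, with min–max
normalized differences and Manhattan distances. Weights land in $[-1, 1]$;
constant features score exactly 0. ReliefF, unlike univariate filters, is
sensitive to conditional dependencies, but rewards correlated relevant
features jointly — factorizing first collapses such correlated blocks into
single metagenes, which is the rationale for the combination.

**Back-mapping.** How a metagene-level ReliefF score names original
features was a genuinely open design point. Gene mode distributes each
metagene's *positive* weight over features proportionally to its loading
column,
$$s(f) = \sum_j \max(w_j, 0)\, \frac{W_{fj}}{\|W_{\cdot j}\|_1},$$
so scores are nonnegative, sum to the total positive component weight
(a conservation property the tests assert), and inherit sparsity from $W$.
Negative component weights are floored at zero rather than subtracted:
a metagene that *splits* classes poorly is uninformative, not
counter-informative, and letting it subtract mass would punish features
merely for loading on a noisy component. Component mode skips the mapping
and returns the top metagenes themselves; both modes are exposed because
either can be the object of interest.

# Parameters that matter

| parameter | default | rationale |
|---|---|---|
| `rank` (r) | `min(50, min(m, n) − 1)` | enough metagenes to isolate small informative blocks while staying under the sample count; always set it explicitly for serious use |
| `k` (ReliefF) | 10, capped at smallest class − 1 (warning) | the canonical ReliefF neighbourhood; an explicit k that reaches a class size is an error |
| `nIterations` | `"all"` | full deterministic pass over samples; subsampling is available (seeded) for very large n |
| `maxIter`, `tol` | 500, 1e-6 | relative decrease of the non-squared Frobenius error; `tol = 0` runs exactly `maxIter` updates (used wherever two implementations must be compared iteration-for-iteration) |
| `nSelect` | — | the number of features reported; sweeps over {5, 10, 20, 30, 40, 50} with 15 repeats are the packaged default grid in `runSweep` |
| classifiers | svm: linear, C = 1; rf: 500 trees; knn: k = 5 | deliberately plain defaults; per-fold min–max scaling is fit on training folds only |

# Numerical choices

- **Initialization**: $W, H \sim \mathrm{Uniform}(0.1, 1.1)$ under the
  user's seed — strictly positive so no entry is absorbed at zero (a zero
  entry is a fixed point of multiplicative updates).
- **Division guard**: $\varepsilon = 10^{-12}$ added to update
  denominators.
- **Restarts for exact recovery**: multiplicative updates converge
  sublinearly and are only locally convergent; on exactly factorizable
  matrices of rank ≥ 2 a single random start frequently stalls above
  Frobenius error $10^{-6}$ within 500 iterations. Where the exact
  factorization itself is the point (tests, the acceptance script), the
  best of 5 seeded starts is used — each run within the same iteration
  budget — which is the standard multi-start practice for NMF.
- **Tie-breaks**, all deterministic: equal ReliefF/selection scores →
  ascending feature index; equal neighbour distances → ascending sample
  index; equal isoform lengths → lexicographically smallest transcript id;
  SVM-RFE equal squared weights → lower index eliminated first.
- **Degenerate inputs**: negative entries are an error for NMF routes (the
  CLI offers `--shift-to-zero`); constant features get normalized diff 0
  (not NaN); zero-variance features correlate 0 with a warning in
  `featureCorrelation`; single-class labels are an error everywhere a
  contrast is required.
- **PCA sign convention**: each component's largest-magnitude loading is
  made positive, so PCA-ReliefF output is reproducible across BLAS
  implementations.

# Metric conventions

Accuracy and the rank-based AUC are standard:
$ACC = (TP+TN)/\text{total}$ and
$AUC = (\#\{s^+ > s^-\} + \tfrac12 \#\text{ties}) / (n^+ n^-)$.
For sensitivity/specificity two conventions are computable, because
published tables in this area sometimes print the nonstandard pair
$SEN = TP/(TP+FP)$ (precision) and $SPE = TP/(TP+FN)$ (recall).
The default is `"standard"` ($SEN = TP/(TP+FN)$, $SPE = TN/(TN+FP)$);
`"as_printed"` reproduces the nonstandard pair, and every `EvalReport`
records which was used. Note the two conventions' sensitivities coincide
when $FP = FN$, but the specificities additionally require $TP = TN$ —
the printed specificity is TP-based, the standard one TN-based.

# Evaluation protocol

Stratified k-fold cross-validation (default 5), repeats re-shuffled from
`seed + repeat − 1`. When a `selectorSpec` is passed, selection is re-fit
on every training fold, so no test sample ever influences which features
are evaluated — the leakage-safe default. Passing a fixed
`SelectionResult` instead reproduces the laxer protocol (selection sees
all samples before CV); it is available deliberately, for measuring how
much that laxity inflates metrics. Component-space selections are applied
to held-out folds through the training fold's own projection (PCA
rotation, or NMF fold-in with $W$ fixed).

One caveat learned from the null experiments: on a *single* fixed dataset
with permuted labels, cross-validated AUC is centred at 0.5 only over
re-permutations; any one permutation retains a chance association with
the data (spread ≈ 0.1–0.13 at 30–100 features × 60 samples). The
leakage tests therefore either average over permutations or use wide
chance bands.

# The synthetic generator

`simulatePlantedMatrix` emulates the two target regimes:

- **Gene-family copy numbers**: negative binomial with baseline mean
  $\mu_0 = 5$ and dispersion $\phi = 0.5$ (variance $\mu + \phi\mu^2$,
  i.e. SD ≈ 4.2 at the baseline) — small overdispersed counts typical of
  family sizes. Poisson is available as the equidispersed variant.
- **Microarray-style intensities**: Gaussian with SD 1 clipped at zero.

A planted subset of features has its positive-class mean shifted by
`effectSize` baseline SDs; all other features are identically distributed
in both classes. The planted indices travel in the object's metadata, so
recovery — the fraction of planted features a selector places in its
top-n — is computable exactly.

What the generator does *not* emulate: correlation between families
induced by shared phylogeny (features are independent given class),
sample-to-sample library-size effects, batch structure, and
heavy-tailed microarray noise. Passing tests therefore demonstrate
correctness of the algorithms and calibration of the harness on
independent-feature data, not performance on real genomes.

# Problem sizes

The packaged tests and the acceptance script run at desk scale, chosen to
exercise every code path with stable statistics: NMF oracle comparisons on
up to 50 × 50 matrices (ranks 1–10); ReliefF oracle equivalence on
enumerable instances (≤ 8 samples, ≤ 3 features; values kept dyadic so
distance ties are exact and the 1e-12 agreement bound is meaningful);
planted-feature recovery at 1000 features × 100 samples, 10 informative,
effect 3, over 15 generator seeds, with the effect-0 control at the same
size; and the pure-noise leakage guard at 100 × 60 over 15 CV repeats.

# Known limitations

- NMF reaches a local optimum; different seeds give different factor pairs
  (the objective value is stable far earlier than the factors are). Results
  always record their seed.
- The rank $r$ is not estimated; it is a parameter. Cross-validating the
  whole pipeline over ranks is possible with `runSweep` but costly.
- SVM-RFE is binary-only, matching its benchmark usage here; multiclass
  evaluation is likewise out of scope for the harness (ReliefF itself is
  multiclass).
- mRMR uses 3 equal-frequency bins for mutual information; heavily tied
  count features can collapse to fewer effective bins.
- Gene-family matrix construction consumes an existing gene→family
  assignment table; homology search and family curation are upstream of
  this package.
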