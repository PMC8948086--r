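---
title: "Donor-level embedding of single-cell expression profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor-level embedding of single-cell expression profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cellular-heterogeneity tools (PCA/tSNE/UMAP) embed *cells*; comparing
cohorts needs the opposite: an embedding of *donors*. The conventional
route builds a donor-by-subset matrix through gating, which requires
biological annotation and discards everything the gates ignore. kernelDEEF
instead treats each donor's cell population as a sample from a probability
distribution over marker/gene space and compares the distributions
themselves, with no subset annotation at any step. The output is a
donor-by-feature matrix usable by any downstream multivariate method.

## The model

**Inner products by kernel mean embedding.** From each donor we pick $n$
cells without replacement (a common $n$ across donors — in practice the
cohort minimum). With cell expression vectors $x_{ik}$ the inner product
between donors $i$ and $j$ is estimated by

$$\langle p_i, p_j \rangle = \frac{1}{n^2}\sum_{k=1}^{n}\sum_{l=1}^{n}
K(x_{ik}, x_{jl}), \qquad
K(x, y) = \exp\left(-\gamma\,\lVert x - y\rVert^2\right).$$

$\gamma$ defaults to $1/p$, with $p$ the number of features entering the
kernel: the marker count for cytometry, the filtered gene count for a
pooled scRNA-seq embedding, and $1$ for the per-gene scan. This is the
median-heuristic-free automatic choice used throughout; it is overridable
in every entry point.

**DEEF coordinates.** With $G$ the $N \times N$ donor Gram matrix, form
$P = \tfrac{1}{2}\log G$ (elementwise log; defined because RBF inner
products are strictly positive) and take the symmetric eigendecomposition
$P = V \Lambda V^\top$. The $i$-th coordinate axis is
$\theta_i = v_i \sqrt{|\lambda_i|}$, and axes are ordered by *signed*
eigenvalue from the largest positive ($\theta_1$) down to the most
negative. $P$ need not be positive semi-definite, so negative eigenvalues
are expected and meaningful; the reconstruction identity is
$\sum_i \operatorname{sign}(\lambda_i)\, \theta_i \theta_i^\top = P$,
which is the suite's core oracle. Consequently the eigenvalue signs are
always written next to the coordinates and never dropped.

**Supervised workflow.** Only positive-eigenvalue axes enter
classification. Per resampling: subsample all donors (training *and*
test — the embedding is unsupervised, so this leaks no labels; the
label-permutation control test asserts it), embed jointly, then tune a
gradient-boosted-tree classifier by 5-fold CV over tree depth
$\{2,3,4,5\}$ and, incrementally from 1, the number of leading axes,
stopping once the best CV score has gone unimproved for more than 11
consecutive axis counts. 25 such resamplings vote by majority. Cohorts
measured under several conditions are handled by fixing the per-condition
axis count first and concatenating the per-condition blocks column-wise.

**Differential distributed genes (DDG).** Per gene, the same machinery in
one dimension ($\gamma = 1$): embed donors by that single gene's
expression distribution, keep the top two axes, and score label
separation by Wilks' $\Lambda = \det E / \det(E + H)$ (within vs total
SSCP). Small $\Lambda$ = strong separation, which can reflect mean,
variance or shape differences — the point of DDG over bulk DEG. The null
is a pooled single permutation: one label shuffle per gene,
giving a null $\Lambda$ sample of the same size for QQ comparison. No
multiple-testing correction is applied; the scan exposes raw values.

**Grid-density route.** As a cross-check, inner products can instead be
computed from kNN density estimates on a per-feature trimmed grid
(range = pooled 15th–85th percentiles by default, 10 bins per feature,
$k = 100$), normalized to sum to 1 and combined by plain dot products.
It is exponential in $p$ and guarded accordingly; its role here is the
concordance check against the kernel route, not production use.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `n_cells` | 1000 (classify), cohort-min in general | cells per donor entering the inner-product estimate |
| `gamma` | `1/p` | RBF bandwidth |
| asinh cofactor | 5 | cytometry normalization `asinh(x/5)` |
| QC thresholds | 200 / 7000 / 70000 / 10% | detected-gene bounds, count ceiling, mito % (all strict) |
| scale factor | 10{,}000 | log normalization `ln(1 + count/total * sf)` |
| pooled-sum filter | 15{,}000 | per-gene total expression across all cells/donors (strict >) |
| grid `alpha`, `bins`, `k` | 0.15, 10, 100 | trim percentile, bins/feature, kNN neighbour count |
| `n_estimators`, depth grid | 5000, {2,3,4,5} | boosting rounds, CV'd tree depth |
| `patience` | 11 | non-improving axis counts tolerated |
| `n_resamplings` | 25 | ensemble size (odd, so binary votes cannot tie) |

## Numerical and design choices

- **Eigenvector signs** are indeterminate; each axis is flipped so its
  largest-magnitude entry is positive, making runs bit-reproducible.
  Near-equal eigenvalues are flagged (`tied_axes`): only their span is
  identifiable.
- **Zero eigenvalues** (within `1e-10 * max|λ|`) stay in the decomposition
  but are excluded by `positive_axes`.
- **Seeds.** Every workflow takes one master seed; per-donor, per-rep and
  per-gene seeds are derived by seeding R's generator with the master seed
  and drawing integers — one integer reproduces a whole run. Internal
  seeding saves and restores the caller's RNG state.
- **Equal `n` is enforced** (the estimator divides by $n^2$); an
  $n_i \times n_j$ variant is deliberately not exposed.
- **Kernel evaluation is blocked/tiled**, bounding memory at block² doubles
  with results identical to the naive computation (tested).
- **Per-gene Gram matrices** compress each donor's gene column to
  (unique value, tie-count) pairs before the pairwise kernel sum —
  algebraically identical to the $n^2$ double loop, verified against it.
- **kNN density**: the standard estimate $\propto k/(n V(r_k))$; since
  vectors are renormalized, constants cancel and $1/r_k^p$ is used.
  $r_k = 0$ points take the maximum finite density (logged); zero grid
  inner products are floored at $10^{-3}\times$ the smallest positive
  entry before the half-log, with a warning.
- **Patience counter** resets after every improvement
  (consecutive-since-last-improvement reading); grid-search ties prefer
  the smaller depth, then fewer axes.
- **Top two θ in the DDG scan** are the first two axes in signed order by
  default — the per-gene step places no positivity restriction, unlike the
  classification workflow; a positive-only variant is exposed.
- **QC boundaries are strict** on all four criteria, so boundary cells
  (exactly 200 detected genes, exactly 10% mitochondrial) are retained.
- **Degenerate genes** (e.g. constant expression in every donor) yield a
  singular scatter; their $\Lambda$ is a flagged `NA` excluded from
  ranking, never silently dropped mid-scan.
- **Learner**: the boosted-tree learner is a pluggable `fit/predict`
  interface. The built-in reference is a compact second-order
  gradient-boosting implementation (logistic loss, shrinkage 0.3, L2 leaf
  penalty 1) compiled via Rcpp, because no established boosting package is
  available in the target environment; its objective and regularization
  mirror the common library defaults.

## What the synthetic cohorts emulate — and what they do not

`simulate_cytometry_cohort` draws each donor's cells from a Gaussian
mixture whose components stand in for cell subsets; the reference cohort
(`default_cytometry_spec`) has three subsets (weights 0.5/0.3/0.2, unit
covariance), a group-B shift of one subset's mean by 3 within-subset sd,
and per-donor jitter of every component mean (sd 0.2) so donors are
exchangeable within group but not identical. Acceptance cohorts generate
1500 cells per donor and subsample $n = 500$, so resampling repetitions
draw genuinely different cells (with a 500-cell pool and $n = 500$,
"resampling" would be a row permutation and stability checks would be
vacuous).

`simulate_scrnaseq_cohort` uses per-gene negative-binomial counts
(log-normal base means, log-normal dispersions, small per-donor log-normal
random effects) with three group-effect classes: `mean_shift`
(multiplicative), `variance_shift` (dispersion inflated, mean untouched)
and `bimodality_shift` (two modes at mean $(1 \pm e)$, mean matched) — the
latter two encode "same average, different distribution", the situation
DDG exists for. Ground truth is returned with the cohort.

Not emulated: spillover/compensation structure, batch effects, ambient
RNA, doublets, gene–gene correlation, library-size confounding between
groups. A green suite therefore establishes that the estimator, the
decomposition and the workflows behave as specified on data with the
assumed structure — not that any particular biological dataset will
separate.

## Runtime scaling in the test suite

The reference boosting round count (5000) is sized for real cytometry
cohorts; with 20–40 synthetic donors and a handful of informative axes,
100 rounds already saturate accuracy, so the acceptance tests run the
identical search/ensemble machinery with `n_estimators = 100` to stay
inside the suite's runtime budget. Nothing else is scaled.

## Known limitations

- The inner-product estimate is biased upward on the diagonal for small
  $n$ (the $k = l$ kernel terms equal 1); the decomposition uses the
  matrix as estimated.
- The single-permutation null is pooled across genes; it calibrates the QQ
  comparison, not per-gene p-values.
- The grid route is for few markers by construction (`bins^p` guard).
- Multi-class vote ties are possible with > 2 labels; they are broken by
  mean predicted-class frequency then lexicographically, and flagged.
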