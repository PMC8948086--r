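# kernelDEEF

Completely data-driven comparison of multiple high-dimensional single-cell
expression profiles (flow/mass cytometry or scRNA-seq). Instead of gating
cells into annotated subsets and counting them, each donor's cell
population is treated as a sample from a probability distribution, and the
cohort is converted into a donor-by-feature matrix directly from those
distributions — no biological assumptions at any step. The matrix then
feeds two bundled workflows: supervised donor-label classification and
per-gene differential-distributed-gene (DDG) analysis.

For whom: computational biologists and data scientists who have per-donor
cytometry (FCS) or scRNA-seq count matrices with case/control (or other)
labels and want donor-level comparisons, predictions, or distribution-aware
gene rankings without designing gating strategies.

## The method

1. **Kernel mean-embedding inner products.** Pick `n` cells per donor
   without replacement and estimate, for every donor pair,

   ⟨p_i, p_j⟩ = (1/n²) Σ_k Σ_l K(x_ik, x_jl),  K(x, y) = exp(−γ‖x − y‖²),

   with γ = 1/p by default (p = feature count).

2. **DEEF decomposition.** Eigendecompose P = ½·log⟨p_i, p_j⟩ (elementwise
   log). Axis i is θ_i = v_i·√|λ_i|, ordered by signed eigenvalue from the
   largest positive (θ1) downwards; negative eigenvalues are expected and
   their signs are always kept next to the coordinates
   (Σ sign(λ_i)·θ_iθ_iᵀ = P).

3. **Workflows.** Classification: positive-eigenvalue axes → gradient-
   boosted trees with 5-fold-CV grid search over tree depth and an
   incremental search over how many leading axes to use (stop after 11
   non-improvements), repeated over 25 cell resamplings and combined by
   majority vote; multi-condition cohorts concatenate per-condition θ
   blocks. DDG: per gene, a 1-D embedding (γ = 1) → top two θ → Wilks'
   Λ = det(E)/det(E+H), with a one-permutation-per-gene pooled null and a
   QQ table; genes are ranked by Λ ascending.

A grid-density route (trimmed per-marker grids, kNN density, vector inner
products) is included as a low-dimensional cross-check of the kernel
estimator.

## Worked example

```r
library(kernelDEEF)

# two groups x 5 donors; three cell-subset mixture components, one subset
# mean shifted 3 sd in group B
sim <- simulate_cytometry_cohort(default_cytometry_spec(
  n_donors_per_group = 5, n_cells_per_donor = 800, seed = 42))

dec <- embed_cohort(sim$profiles, kernel_config(n_cells = 400),
                    master_seed = 42)
dec
#> <theta_decomposition> 10 donors, 9 positive axes; leading eigenvalues: 0.368, 0.0572, 0.0336, 0.0192 ...
round(dec$theta[, 1:2], 3)
#>    theta1 theta2
#> A1 -0.185 -0.025
#> A2 -0.199  0.153
#> A3 -0.190 -0.097
#> A4 -0.200  0.046
#> A5 -0.205 -0.072
#> B1  0.206  0.022
#> B2  0.160 -0.036
#> B3  0.198  0.038
#> B4  0.197  0.062
#> B5  0.174 -0.096
cor(dec$theta[, 1], as.integer(sim$labels))
#> [1] 0.998
```

θ1 alone separates the groups: the shifted cell subset moves every group-B
distribution coherently, and the leading eigenvalue (0.368, an order of
magnitude above the rest) carries that contrast. The remaining axes mop up
donor-level variability. `positive_axes(dec)` feeds `ensemble_predict()`
for classification; `ddg_scan()` runs the per-gene workflow on scRNA-seq
profiles after `qc_filter_cells()`, `log_normalize()` and
`filter_genes_pooled_sum()`.

A command-line wrapper for manifest-driven runs (subcommands `embed`,
`classify`, `ddg`) is installed at `inst/cli/kerneldeef.R`; outputs are
TSV tables plus a `run_record.json` capturing every seed and parameter.

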