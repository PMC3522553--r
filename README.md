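# cmfqsar

Collaborative multi-cell-line QSAR by collective matrix factorization.

## The problem

Panels of candidate inhibitors — for example cyclopamine-derivative
antagonists of the Hedgehog signaling pathway — are often assayed against
several related cell lines. Each single cell line yields too few, too noisy
activity measurements (PKi magnitudes derived from IC50 via the Cheng–Prusoff
conversion) to support a reliable quantitative structure–activity relationship
(QSAR) model on its own. But the columns of the compound × cell-line activity
matrix are far from independent: the same compounds act through the same
molecular mechanisms. `cmfqsar` treats multi-cell-line QSAR as a collaborative
filtering problem: held-out or unmeasured activities are the "missing ratings"
of a recommender system, predicted from the observed cells of *all* columns at
once, plus the compounds' structural descriptors.

## The model

Let `X` (m compounds × n cell lines) be the nonnegative activity matrix with
observation indicator `I`, and `Y` (m × r) the complete compound descriptor
matrix. Collective matrix factorization seeks low-rank factors `U` (m × d),
`V` (n × d), `W` (r × d), sharing the compound factors `U` between both
reconstructions `X ≈ U Vᵀ` and `Y ≈ U Wᵀ`, by minimizing

    L(U,V,W) = ½‖I ∘ (X − U Vᵀ)‖²_F + (λ₁/2)‖Y − U Wᵀ‖²_F
               + (λ₂/2)(‖U‖²_F + ‖V‖²_F + ‖W‖²_F)

with gradient descent and a step-halving line search (step size reset to 1
each iteration and halved until the objective strictly decreases). Missing
activities are then read off `U Vᵀ`.

Around the core model the package provides:

* **Partitioning** — repeated seeded random 2/3–1/3 splits, and a
  deterministic *Diverse Subset* partition built from a greedy maximin
  diversity ranking of the descriptors.
* **Evaluation** — RMSE and R² against per-cell-line ridge regression and SVR
  baselines scored on identical test cells, with a paired Wilcoxon
  significance report, plus a regularization × training-ratio sweep.
* **Feature weighting** — a three-step collaborative scheme: per-feature
  Shannon entropy (inter-cell-line information), per-(cell line, feature)
  dependency (|Pearson r| for quantitative features, contingency coefficient
  for qualitative ones), and their product as the final weight matrix `Z`
  (n × r).
* **Applicability domain** — leverages `hᵢ = xᵢᵀ(XᵀX)⁻¹xᵢ`, the warning
  threshold `h* = 3k/n`, standardized residuals, and Williams-plot outlier
  flags.
* **Synthetic generators** — seeded low-rank, shared-latent, and a
  93 × 4 × 28 drug-like-index-shaped benchmark fixture, all with emitted
  ground truth.

## Worked example

Four cell lines whose activity columns share 90% of their latent structure,
90 compounds, deliberately noisy descriptors — the regime where borrowing
strength across columns matters:

```r
library(cmfqsar)
sim <- simulate_shared_latent(m = 90, n = 4, d = 2,
                              cross_column_signal = 0.9, seed = 1)
rep <- run_comparison(sim$activity, sim$descriptors, protocol = "random",
                      repeats = 10, seed = 1,
                      methods = c("cmf", "ridge", "svr"),
                      control = cmf_control(d = 2, max_iter = 300))
print(rep)
#> comparison_report (random, 10 repeat(s))
#>   cell_line method      rmse r_squared
#>  cellline_1    cmf 0.1564914 0.9065366
#>  cellline_2    cmf 0.1210867 0.6821443
#>  cellline_3    cmf 0.1942667 0.8721255
#>  cellline_4    cmf 0.2297569 0.8543817
#>  cellline_1  ridge 0.3306720 0.5724830
#>  cellline_2  ridge 0.1690191 0.3878462
#>  cellline_3  ridge 0.3401735 0.5948780
#>  cellline_4  ridge 0.4031232 0.5473276
#>  cellline_1    svr 0.4189733 0.3366729
#>  cellline_2    svr 0.1945731 0.1923334
#>  cellline_3    svr 0.4186539 0.4139544
#>  cellline_4    svr 0.4719272 0.3987044
```

Joint factorization roughly halves the held-out RMSE of either single-column
baseline and lifts R² substantially in every cell line; the paired Wilcoxon
test (`method_significance(rep)`) gives p ≈ 0.002 for every (cell line,
baseline) pair over the 10 repeats.

Feature weighting on the drug-like-index-shaped fixture, whose activities are
driven by 5 planted count features and whose feature 18 is absent from every
compound:

```r
sim <- simulate_dli_fixture(seed = 42)
w <- weight_matrix(sim$activity, sim$descriptors)
print(w)
#> feature_weight_report: 28 features x 4 cell lines
#> top features by mean final weight: DLI7, DLI1, DLI21, DLI3, DLI19
sort(sim$truth$signal_features)
#> [1]  1  3  4  7 21
w$final[, "DLI18"]
#>   BxPC-3 NCI-H446   SW1990 NCI-H157
#>        0        0        0        0
```

Four of the five planted signal features rank in the top five by final
weight, and the structurally absent feature gets weight exactly 0 in every
cell line (its entropy is 0 bits).

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/cmfqsar.R`): subcommands `simulate`, `fit`, `predict`, `split`,
`evaluate`, `sweep`, `weights`, `doa`; see `?cmf_cli`.

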