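---
title: "Methods: collective matrix factorization for multi-cell-line QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collective matrix factorization for multi-cell-line QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmfqsar)
```

## The model and its assumptions

A compound panel assayed against several cell lines gives a compound ×
cell-line activity matrix $X \in \mathbb{R}_{\ge 0}^{m \times n}$ (activities
are PKi magnitudes, `pki_magnitude()`, hence nonnegative) with an observation
indicator $I$ marking which cells were measured, and a complete compound ×
descriptor matrix $Y \in \mathbb{R}^{m \times r}$. Collective matrix
factorization (CMF) assumes both matrices are generated from the *same*
low-dimensional compound representation: latent factors $U$ ($m \times d$),
$V$ ($n \times d$), $W$ ($r \times d$) with $X \approx UV^\top$ and
$Y \approx UW^\top$, $d \le \min(m, n, r)$. The joint objective is

$$
L(U, V, W) = \tfrac12\lVert I \circ (X - UV^\top)\rVert_F^2
+ \tfrac{\lambda_1}{2}\lVert Y - UW^\top\rVert_F^2
+ \tfrac{\lambda_2}{2}\left(\lVert U\rVert_F^2 + \lVert V\rVert_F^2
+ \lVert W\rVert_F^2\right).
$$

The key modeling assumptions are (i) a shared low-rank structure across cell
lines — the columns of $X$ are correlated because they arise from the same
compounds acting through related mechanisms — and (ii) descriptors that are
informative about the same latent representation, so the $Y$ term acts as
structured side information rather than the primary signal. When assumption
(i) fails (independent columns), CMF degrades gracefully toward per-column
factorization and has no advantage over single-cell-line regression.

Two points the formulation deliberately leaves open, and how this package
resolves them:

* **Nonnegativity of the factors.** The data matrix $X$ is validated
  nonnegative, but the fitting algorithm contains no projection step, so the
  factors themselves may go negative during optimization. We follow the
  algorithm as specified rather than adding a projection; predictions of
  genuinely nonnegative data from a good fit are in practice nonnegative or
  negligibly below zero.
* **The dual role of $\lambda_1$.** In the single-matrix objective
  (`objective_basic()`) $\lambda_1$ penalizes $U$; in the joint objective it
  weights the $Y$-reconstruction term. Both are implemented exactly as
  written; they are different objectives and the symbols are not
  interchangeable across them.

## The optimizer

`fit_cmf()` is plain gradient descent with a backtracking line search. With
$E = I \circ (UV^\top - X)$ and $F = UW^\top - Y$:

$$
\nabla_U L = E V + \lambda_1 F W + \lambda_2 U,\qquad
\nabla_V L = E^\top U + \lambda_2 V,\qquad
\nabla_W L = \lambda_1 F^\top U + \lambda_2 W.
$$

Because $Y$ is required to be complete, no indicator enters the $Y$ term. The
gradients are validated against central finite differences of the objective
(step $10^{-6}$, relative tolerance $10^{-5}$) on a battery of seeded random
instances; this oracle is what pins down the parenthesization of the update
equations.

Each outer iteration recomputes the gradients, resets the step size to
$\gamma = 1$, and halves $\gamma$ until the simultaneous update of all three
factors *strictly* decreases the objective, up to `max_halvings` (default 50)
halvings; exhausting the budget terminates the fit with
`stop_reason = "line_search_stalled"`. Otherwise iteration continues until
`max_iter` ($T$) steps or until the absolute decrease falls to `tol`
($\varepsilon$) or below. The objective trace is therefore strictly
decreasing by construction — a property the test suite asserts on every fit
it runs.

Defaults: $d = 3$ (with $n = 4$ cell lines, $d \le 4$ is forced; 3 leaves
headroom below the bound), $\lambda_1 = \lambda_2 = 0.1$ (the middle of the
sweep grid below, where the sweep shows performance is flat), $T = 500$,
$\varepsilon = 10^{-6}$, `init_scale = 0.1` (uniform $[0, 0.1]$ seeded
initialization — small positive values so the first iterations are governed by
the data terms rather than the ridge). Initialization requires an explicit
seed; there is no hidden RNG state, and all generators and fitters are pure
functions of their arguments including the seed.

Numerical notes: unobserved cells are stored as `NA` but enter the computation
as zeros multiplied by the mask, so the masked values can never leak into a
fit (a test zeroes them and asserts bit-identical predictions). A non-finite
candidate objective during line search counts as a failed step and triggers
further halving.

## Evaluation protocol

`run_comparison()` reproduces the two-protocol comparison harness. For each
cell line $j$ and repeat: the compound set is split (random seeded 2/3–1/3, or
the deterministic Diverse Subset partition); ridge and SVR train on the
training compounds' descriptors against the observed training activities of
column $j$ alone; CMF masks the *test cells of column $j$ only* and fits on
everything else — the rest of column $j$ plus all other columns — once per
(column, repeat). All methods are scored with RMSE and $R^2$
($1 - SS_{err}/SS_{tot}$, which may be negative) on the identical observed
test cells. Baselines use descriptors z-scored by training-set statistics
only; ridge is solved in closed form with an unpenalized intercept
($\alpha = 1$ by default), SVR delegates to a radial-kernel support vector
machine with library defaults. Claims of improvement are accompanied by a
paired two-sided Wilcoxon signed-rank test over per-repeat metrics
(`method_significance()`), reported but never used as a decision gate.

`sweep_regularization()` evaluates $\lambda_1 = \lambda_2 = \lambda$ over the
grid $\{0.001, 0.01, 0.1, 1, 10, 100\}$ against training ratios
$\{15\%, 35\%, 55\%, 75\%\}$ of observed cells. For each (ratio, seed) the
held-out cells are drawn once per column — leaving at least two observed
cells per column — and reused across all $\lambda$ values, so the grid
comparison is paired; RMSE pools the held-out cells of all cell lines.

## Partitioning

`diversity_ranking()` implements greedy maximin diversity ranking: the first
table row is the reference; each subsequent rank goes to the compound whose
minimum distance to all already-ranked compounds is largest. Open choices
resolved here: the metric is Euclidean distance on per-feature z-scored
descriptors (zero-variance features contribute nothing), because raw
drug-like-index counts differ in scale by orders of magnitude and would
otherwise dominate; ties break to the lowest row index, making the ranking
deterministic. An exhaustive plain-loop oracle checks the ranking exactly for
all tables up to $m = 10$. `diverse_split()` assigns the *head* of the
ranking (the most diverse, representative compounds) to training by default —
training on the spanning subset and testing on the interior is the reading
that keeps "representative and distinct characteristics" in the training set —
with `test_side = "head"` available to flip the direction.

## Feature weighting

`weight_matrix()` builds the $n \times r$ weight matrix $Z$ in three steps:

1. **Entropy (inter-cell-line).** Shannon entropy in bits of each feature's
   discretized empirical distribution. Discretization is the open choice
   here: integer-valued features — all 28 drug-like-index counts — use their
   distinct values as bins (natural for counts and shift-invariant);
   continuous features fall back to 10 equal-width bins. Entropy is
   unnormalized by default with a `normalize` flag dividing by
   $\log_2(\#\text{bins})$; only the *relative* ordering of weights matters
   downstream, so the scale convention is cosmetic.
2. **Dependency (intra-cell-line).** Per (cell line, feature), computed on the
   compounds observed in that cell line: absolute Pearson correlation for
   quantitative features (zero if either side is constant), Pearson's
   contingency coefficient $C = \sqrt{\chi^2/(\chi^2 + N)}$ on the feature ×
   activity-quartile table for qualitative features (zero for degenerate
   tables). Quartile binning of the activities is the conventional default
   for giving the contingency table a categorical second margin.
3. **Product.** $z_{ij} = H_j \cdot \text{dep}_{ij}$, exactly — asserted as an
   identity in the tests.

A feature identical across all compounds has entropy 0, dependency 0, and
final weight exactly 0 in every cell line; the 93 × 4 × 28 synthetic fixture
plants such a feature at column 18 and the acceptance machinery recomputes
its weight from scratch.

## Domain of applicability

`leverages()` computes $h_i = x_i^\top (X^\top X)^{-1} x_i$ on the raw
(uncentered) training descriptors, matching the formula as stated; a `center`
flag is available. A rank-deficient Gram matrix — guaranteed whenever a
descriptor column is identically zero, as in the fixture — falls back to the
Moore–Penrose pseudoinverse with a warning. The warning leverage is
$h^* = 3k/n_{\text{train}}$. `williams_table()` standardizes the supplied
residuals by their own root-mean-square (the residual $\sigma$ unit; an
all-zero residual vector standardizes to zeros) and flags structural outliers
($h > h^*$) and response outliers ($|RES| > 3\sigma$). The residuals fed in
are the held-out prediction residuals of whatever model is being audited;
note that with $q$ residuals standardized by their own RMS, a single outlier
can reach at most $\sqrt{q}$, so the $3\sigma$ flag is only informative with
$q \gtrsim 10$ test compounds.

## Synthetic data: what it emulates and what it does not

Three generators supply every test's ground truth; all are pure functions of
their arguments including the seed.

* `simulate_lowrank()` draws factors as absolute values of standard normals,
  adds optional Gaussian noise (X is clipped at 0 afterward; default noise
  levels keep clipping below ~1% of cells), and masks a per-column fraction of
  cells. Zero-noise instances admit essentially exact recovery — the
  acceptance suite requires held-out RMSE below $10^{-2}$ at
  $m{=}60, n{=}4, r{=}10, d{=}2$ with 30% of one column masked, $\lambda_1 =
  1$, $\lambda_2 = 10^{-6}$, median over 5 seeds (observed: ~$10^{-6}$).
* `simulate_dli_fixture()` emulates the *shape* of the motivating panel: 93
  compounds, cell lines BxPC-3, NCI-H446, SW1990, NCI-H157, 28 integer count
  features with Poisson marginals (gamma-distributed means, mean ≈ 4), column
  18 identically zero, activities a nonnegative linear function of 5 planted
  features (standardized to a PKi-like level of 6 ± ~1, noise sd 0.3, clipped
  at 0), full mask. The planted coefficients are emitted so tests can assert
  signal recovery.
* `simulate_shared_latent()` interpolates between independent activity columns
  (`cross_column_signal = 0`) and columns identical up to positive per-column
  scaling (`= 1`), with descriptors tied to the latent factors but carrying
  substantial noise (sd 1 by default against signal entries of order 1).
  Those defaults are the point of the design: the descriptors alone support
  only a mediocre regression, while at high sharing the other columns nearly
  determine a held-out column, so the generator isolates exactly the
  collaborative gain the joint factorization is supposed to deliver. The
  acceptance suite requires CMF to beat per-column ridge in at least 8 of 10
  seeds at `cross_column_signal = 0.9` (observed: 10 of 10).

None of these generators emulates real cyclopamine-derivative chemistry:
descriptor columns are independent given the latent factors, count marginals
are Poisson rather than empirical, and activity noise is homoscedastic
Gaussian. Passing tests therefore demonstrate the correctness and the
qualitative behavior of the *method* — monotone descent, exact gradients,
recovery under the model's own assumptions, collaborative gain when columns
share structure — not predictive performance on laboratory data.

## Problem sizes and determinism

The test and acceptance workloads are sized for interactive runs: gradient
oracles on instances up to $10 \times 4 \times 6$, recovery at $m = 60$,
comparisons at $m = 90$ with 300-iteration fits, and the 6 × 4 sweep at
$m = 60$ over 3 seeds — the full suite completes in well under a minute.
Every stochastic routine takes an explicit seed and restores the caller's RNG
state (`withr::with_seed`), so runs are reproducible end to end, including
from the command line where the resolved configuration and seed are always
logged.

## Known limitations

* Gradient descent with a shared step size for $U, V, W$ converges slowly on
  badly scaled problems; there is no adaptive preconditioning and no
  alternating least squares path.
* The objective is non-convex; different seeds reach different local minima.
  The evaluation harness treats the seed as part of the protocol.
* $R^2$ is undefined for constant observed test vectors; the comparison
  harness records `NA` for such (tiny) cells rather than failing.
* Qualitative-feature dependency needs enough observed activities per cell
  line to populate a contingency table; with fewer than ~8 observations the
  quartile binning degenerates and the dependency is reported as 0.
* The Williams-plot residual standardization uses the residuals' own RMS;
  see the $\sqrt{q}$ ceiling noted above.
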