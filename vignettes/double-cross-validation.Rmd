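---
title: "Double cross-validation: model selection, model assessment, and the bias–variance anatomy of its errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double cross-validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublecv)
```

## The procedure and its assumptions

`doublecv` implements repeated double (nested) cross-validation for
regression when the model itself is uncertain — when descriptors must be
selected, a principal-component rank tuned, or a penalty chosen. The outer
loop draws `n_outer` random partitions of the sample into a training set and
a test set of size `n_test`. On each training set the inner loop runs a full
model-selection procedure; the chosen configuration is then refit on the
whole training set and assessed on the test rows only. Because the test rows
never influence the search, the per-partition errors `PE_k` are free of
model selection bias, and their average `PE_dcv` estimates the prediction
error of the *modelling process* at training size `n_train = n − n_test`.
Note the implication: double cross-validation validates the process of
arriving at a model, not one final refit model.

The inner objective is a plain mean squared validation error: each candidate
is refit on every construction set and scored on the corresponding
validation rows, totals divided by the total validation count. For equal
validation sizes this equals the sum-over-splits form `Σ ss / (n_inner ·
n_val)`; for k-fold splits with unequal folds the total-count denominator is
the consistent generalisation. Minimisation is used throughout (never q²):
the selected model's objective is an MSE-type quantity directly comparable
with the outer-loop errors.

Assumptions worth stating: outer partitions are drawn independently, so test
sets of different partitions may overlap — the repeated-split estimator
averages dependent replicates, which is why `vb(PE)`, the scatter of `PE_k`
around `PE_dcv`, matters. With `n_test = 1` and `n_outer = n` the partitions
are enumerated deterministically (outer leave-one-out). Within one
partition, train and test are disjoint by construction.

## Error decomposition against a known population

When data come from a known population `y = Xb + e`, `X` row-wise Gaussian
with covariance `V` and `e ~ N(0, σ²)`, the package computes, per outer
record with coefficient estimate `b̂_k`:

* coefficient errors: `mse(b) = mean ‖b̂_k − b‖²`, split into
  `bias(b) = mean ‖E[b̂_k] − b‖²` and `var(b) = mean ‖b̂_k − E[b̂_k]‖²`;
* model errors on test data: the same quadratic forms propagated through
  `X_test,k`, divided by `n_test`;
* theoretical errors: `ME_theo = (b̂_k − b)ᵀ V (b̂_k − b)` (the population
  covariance replaces random test data) and `PE_theo = ME_theo + σ²`. The
  identity `PE_theo − ME_theo = σ²` holds exactly by construction.

The expectations `E[b̂_k]` are conditioned on the *selected* configuration
(technique, subset, rank, training size). For MLR under a Gaussian design
the conditional-expectation argument makes the omitted-variable formula
exact, not asymptotic: `E[b̂_a] = b_a + V_aa⁻¹ V_a,ā b_ā` with `a` the
selected subset and `ā` its complement. For PCR no equally clean closed form
is exposed; a seeded Monte-Carlo estimator (default `n_mc = 2000` fresh
training sets) is the authoritative implementation, and it doubles as the
cross-check oracle for the analytic MLR route in the tests. Entries are
cached by their conditioning tuple, so recurring subsets across partitions
cost one computation. The per-partition definitions do not cancel the
bias×variance cross term in finite samples, so `mse = bias + var` is
asserted only in expectation (3-standard-error Monte-Carlo bands in the
tests), never per run.

`rel.Dev = 100·(ave.PE − ave.PE_theo)/ave.PE_theo` summarises, in percent,
how far the averaged outer-loop estimate sits from the averaged theoretical
truth; underestimation is negative.

## Selectors

**Tabu search (REM-TS) for MLR/PCR.** Per iteration the status of every
variable is flipped once (in → out, out → in) and each resulting candidate
is scored on a split set *shared across all candidates of that training
set* — unshared splits would add pure sampling noise to the comparison. The
best non-tabu move is executed: the most improving if one exists (steepest
descent), otherwise the least worsening (mildest ascent), so the search
climbs out of local optima instead of stopping. Any move recreating a
previously visited subset is tabu; the search is deterministic given the
splits. It starts from the empty subset — the search must then justify every
inclusion, and the empty-model objective (the CV estimate of `var(y)`) is
the natural baseline — and returns the best configuration *visited*, not the
final state. Ties between equally good moves fall to the lowest variable
index. The iteration budget is the only user parameter; the simulation
defaults are 12 iterations for the two-variable population and 36 for the
six-variable one. For PCR, every candidate subset is scored at all ranks
`1 .. min(|subset|, n_constr − 1)` on the same splits and the best rank wins
("co-optimised"); components with negligible singular values are skipped, so
collinear subsets stay finite.

An MLR candidate with `|subset| ≥ n_constr` is infeasible and scores `+Inf`
(the selector then avoids it); rank-deficient but feasible fits use
minimum-norm least squares. Under a leave-one-out inner design the MLR
objective is computed through the exact hat-matrix identity
`e_loo,i = e_i/(1 − h_ii)` — an algebraic shortcut, not an approximation;
the tests pin it to the explicit refit loop at 1e-10.

**Lasso.** The penalty path is evaluated by `n_folds`-fold CV (default 10)
with a deterministic, seed-derived fold assignment; the minimising penalty
is taken (no one-standard-error rule, keeping the selector a pure
error minimiser like the others), and the model is refit on the whole
training set at that penalty. The non-zero coefficients define the subset.

**SA-kNN.** For each subset size `D` in `d_min..d_max` an independent
simulated-annealing run (sub-seeded; the split set is shared) mutates
`m_mutate` descriptors per step and scores candidates by the CV error of
k-nearest-neighbour regression minimised over `k = 1..k_max`. Published
defaults: `T_max = 60`, `T_min = 1e-3`, cooling factor 0.4, 40 steps per
temperature, `k_max = 5`, `D` from 2 to 16. Two details are package
decisions, not published facts: (i) the Metropolis acceptance uses
`ΔE = 100·ΔMSE/var(y)` — the objective expressed as percent of response
variance — because raw MSE units are incommensurate with the published
temperature scale; (ii) the global winner across all `D` is the
configuration with the lowest inner-CV error. Neighbour averaging is
unweighted, in the autoscaled subset space (training statistics applied to
query rows), with distance ties broken by lower training-row index.

## The synthetic generator

`make_population()` fixes the stated world: `p = 21` predictors, `n = 80`
objects, AR(1) predictor covariance `V[i,j] = 0.5^|i−j|`, noise variance
`σ² = 1`, and two coefficient vectors — `b7 = b14 = 1.077` (strong, nearly
uncorrelated pair) and `b6 = b8 = b13 = b15 = 0.343, b7 = b14 = 0.686`
(weak, correlated clusters; the harder selection problem). `X` is generated
as `Z V^{1/2}` with the *symmetric* (eigen) square root — the literal
reading of "square root of the covariance matrix", and orientation-free —
and no intercept enters the generating model; columns are not re-centered
after generation. Oracle sets (default 5000 rows) use a deterministically
decoupled seed stream so a training sample and its oracle never share rows.

One caveat is documented rather than repaired: with these printed
coefficients the implied population R² — `bᵀVb/(bᵀVb + σ²)`,
`population_r2()` — is 0.700 and 0.715 for the two models, not the nominal
0.75 sometimes quoted for them; the printed coefficients are taken as
canonical. The generator emulates Gaussian predictors, a sparse linear
signal and homoscedastic noise only — real descriptor tables bring
non-Gaussian marginals, nonlinear structure, and heteroscedasticity, so a
green test here establishes correctness of the machinery, not performance
on arbitrary real data.

Seed discipline is hierarchical: one study seed spawns per-simulation,
per-partition and per-inner-split seeds through an integer hash
(`derive_seed()`), so the same data are generated for every
selector/design combination within a simulation repeat, and outer partitions
are shared across combinations at a given test size — comparisons are
paired. Results are bit-reproducible from the seed and independent of
evaluation order.

## Numerical and design choices

* **Outer error denominator.** `PE_k` divides by the test-set size
  `n_test`; `vb` statistics divide by `n_outer` (population form).
* **Simulation vs real mode.** Simulation mode fits without intercept or
  scaling (the population is centered and scaled by construction). Real mode
  centers `y` and centers/scales `X` using construction-set statistics only,
  applied to validation and test rows — no leakage. PCR always centers (its
  intercept absorbs the means); kNN always autoscales.
* **Empty subset.** Legal everywhere; denotes the mean-only model
  (prediction = construction-set mean). It is the tabu start state.
* **LMO sizes.** Validation size is round-half-up of `d · n_train`;
  construction sets below 2 rows are rejected.
* **K-fold assignment.** Random permutation, then contiguous chunks with
  sizes differing by at most one.
* **Internal error.** The selected model's `inner_cv_error` is its
  search-time objective on the shared splits (deterministic splits make a
  post-hoc re-evaluation identical).
* **Rank grid truncation.** PCR ranks are additionally truncated at the
  numerical rank of each construction matrix (singular values below
  `1e-10 · s_max` contribute nothing).

## Prefiltering for real descriptor tables

`variance_filter()` removes constant columns always and near-constant
columns by the frequency-ratio rule (most-frequent / second-most-frequent
count above 19 *and* distinct-value fraction below 10%) — the named
filtering step is not defined precisely in the sources, so the rule is
explicit and configurable. `correlation_filter()` removes the *later*
column of every pair exceeding the threshold in a greedy scan (deterministic
and order-stable); its postcondition — no kept pair above the threshold —
is asserted literally in the tests. `car_scores()` returns
`P^{-1/2} ρ_xy` (whitened predictor–response correlations); preselection
ranks by `|CAR|`, since a signed ranking would conflate direction with
importance, and keeps the extremes (defaults 5 high + 45 low, yielding a
pool that contains both relevant and irrelevant predictors on purpose).

## Scale and limitations

The full study grid (200 simulations × 15 test sizes × 5 inner designs ×
several selectors) runs for hours to days on one CPU. `study_config(scale =)`
shrinks `n_sim`, `n_outer` and the LMO repeat counts proportionally
(rounded up, minimum 1); the package's own acceptance checks run the
reduced regime — 30 simulations, 20 outer partitions, 10 inner repeats —
where the unbiasedness of `PE_dcv`, its growth with `n_test`, the
optimism of `PE_internal`, and the decay of `vb(PE)` are all testable
within Monte-Carlo error bands fixed in advance.

Out of scope by design: molecular descriptor computation and SMILES
handling, bootstrap/out-of-bag outer resampling, classification endpoints,
stratified splitting, ridge/elastic-net/PLS, and figure reproduction.
Decomposition expectations are provided for MLR (analytic) and PCR
(Monte Carlo) only; Lasso and kNN have no exposed closed form and their
records are assessed through prediction errors alone.
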