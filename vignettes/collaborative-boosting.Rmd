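---
title: "Collaborative subbagged Gentle Boosting: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative subbagged Gentle Boosting: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(collboost)
```

## The model

`collboost` fits a bi-level binary classifier of `L = S * T` weak learners.
The lower level is a regression stump: one feature, one threshold, and two
real-valued leaves fitted by weighted least squares, so its output is a
confidence in `[-1, 1]` rather than a hard vote. The upper level groups the
stumps into `S` Gentle Boost ensembles of `T` rounds each. Gentle Boost
maintains a probability distribution `w` over its training subset; each
round fits a stump minimizing the `w`-weighted squared error against the
`-1/+1` labels and then reweights multiplicatively,
`w_i <- w_i * exp(-y_i f_t(x_i))` (renormalized), so misclassified
instances gain relative weight and correctly classified ones lose it. The
ensemble output is the stump sum `F(x)`, mapped to a probability by the
sigmoid `g(z) = 1 / (1 + e^-z)` when one is wanted.

Each ensemble trains on its own subsample drawn by stratified sampling
*without* replacement (subbagging) at a fraction `eta` of the data; class
proportions are preserved up to integer rounding via largest-remainder
reconciliation, and subsets are drawn independently of one another, so they
may overlap. The multi-model averages the ensemble totals,
`Phi(x) = (1/S) * sum_j F_j(x)`, and predicts `sign(Phi(x))`, with
`sign(0)` fixed to `+1` for determinism. The reported probability
`g(Phi(x))` applies the per-ensemble sigmoid to the average; this is a
natural extension rather than a derived quantity, and is labeled as such
here.

The margin (or conviction) of a labeled instance is `y * F(x)`: positive
exactly when the instance is classified correctly, with magnitude measuring
confidence. Both collaboration schemes are margin-guided instance
exchanges.

## Weak-learner collaboration (W-CLB)

W-CLB runs *during* boosting, in lock step across the `S` ensembles. After
every round `t`, the scheme makes `n_exc` independent attempts, each firing
with probability `p_c`. A fired attempt is a simultaneous ring exchange:
ensemble `j` removes the correctly classified instance with the *weakest*
conviction under its partial ensemble `F` built so far, and receives the
*strongest*-conviction correct instance of ensemble `j + 1 (mod S)` — so a
single collaboration touches all `S` ensembles, and the expected number of
tentative collaborations over a run is `T * p_c * n_exc`. Design choices
where the procedure was genuinely open:

* **Copy, not move.** The donated instance is copied (the donor keeps it);
  a symmetric swap variant sits behind `wclb_config(swap = TRUE)`. Copying
  keeps selection and replacement independent across ensembles and subset
  sizes constant.
* **Weight inheritance.** The incoming instance inherits the removed
  instance's boosting weight, preserving the probability-distribution
  invariant without a global renormalization.
* **Duplicate guard.** Subsets are samples without replacement, so an
  exchange that would duplicate an instance within a subset is skipped and
  logged as unsuccessful; a self-replacement (the donated instance *is* the
  removed one, possible under margin ties) is likewise a logged no-op.
* **Margins on the cumulative `F`.** Conviction is measured by the partial
  ensemble built so far, not the current round's stump alone.

Removing a weak-margin instance (large `exp(-y F)` term) in favor of a
strong-margin copy lowers the ensemble's empirical exponential loss on its
own subset by construction; that is the sense in which the exchange is
loss-improving. Its effect on *generalization* depends on the data
distribution, and the package's paired-comparison tooling
(`paired_compare()`) exists precisely to measure it rather than assume it.

## Strong-learner collaboration (S-CLB)

S-CLB runs *after* all ensembles are trained. The pairs (initiator `j`,
predecessor `k < j`) are visited in sequence order — `S(S-1)/2` pairs per
pass, a quadratic iteration count — and each pair goes through three steps:
the initiator selects its `n_exc` weakest-conviction correct instances and
the predecessor its `n_exc` strongest; the selections are swapped between
the two subsets (guarded against within-subset duplicates); both ensembles
are retrained from scratch on the modified subsets. The exchange is
**accepted only if the multi-model's empirical 0-1 error on the full
training set does not increase**; otherwise both subsets and models revert
bitwise. Acceptance-on-non-increase makes the empirical-error trace over
the iteration counter `tau` non-increasing *by construction* — harmful
exchanges cannot change the state. Ties are accepted by default so that
error-neutral, margin-improving moves can pass; `sclb_strict = TRUE`
restricts acceptance to strict decreases, and `sclb_loss = "exponential"`
switches the acceptance functional to the mean exponential loss of the
averaged output. One full pass is the default (`sclb_passes` raises it).

Whether the acceptance error should be 0-1 or exponential is ambiguous in
principle; 0-1 is the default because it is the quantity whose monotone
trace the scheme guarantees and reports.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `S` | boosting ensembles | — | collaboration needs `S >= 2` |
| `T` | boosting rounds per ensemble | — | bounds the raw output: `abs(F) <= T` |
| `eta` | subset fraction, `(0, 1]` | 0.5 | subset size `round(eta * N)` |
| `p_c` | W-CLB attempt probability | 0.1 | per repetition, per round |
| `n_exc` | instances per collaboration | 1 | both schemes |
| `seed` | master seed | 1 | subsampling + W-CLB schedule |

Subsampling derives one stream per subset (`seed + j`), so changing `S` or
`eta` does not perturb earlier subsets. All training given the subsets is
deterministic: stump ties break by lowest feature index then lowest
threshold, boundary instances go left, and thresholds sit at midpoints of
consecutive distinct sorted values.

## Numerical choices

* Boosting weights are floored at `1e-300` before renormalization to keep
  the distribution invariant in float arithmetic over long runs.
* The sigmoid uses the overflow-safe two-branch form, since `|F|` can reach
  `T`.
* Stumps with every feature constant degenerate to the weighted mean label
  and are flagged; training continues through them.
* Model JSON is written with 17 significant digits so serialized models
  reproduce in-memory predictions exactly.
* AUROC uses mid-ranks (ties credited 1/2), the Wilcoxon–Mann–Whitney
  statistic.
* k-fold means are reported with a 95% t-interval half-width over folds —
  a conventional choice for fold means, not a claim about the sampling
  distribution of the underlying error.
* Fold assignment deals labels from a global round-robin continuing across
  classes, so `k` may reach `N` (leave-one-out); a held-out fold containing
  a single class gets `NA` for AUROC while its error rate is still counted.

## What the synthetic generator emulates — and what it does not

`gaussian_blobs()` draws two spherical unit-variance Gaussian classes
separated by `overlap` pooled standard deviations along the first axis,
with exact class counts `round(imbalance * n)`. The separation pins the
Bayes error in closed form (`bayes_error()`): for balanced classes
`pnorm(-overlap / 2)`, e.g. about 0.10 at `overlap = 2.56`. That makes
quantitative claims testable without any external data: a competent
classifier's test error should approach the closed form from above.

The generator deliberately does *not* emulate the feature statistics of
real tabular benchmarks or of gel-electrophoresis texture features:
correlated features, heavy tails, label noise, and non-axis-aligned class
boundaries are all absent. Passing tests on blobs therefore demonstrate the
*mechanics* of the method (exchange accounting, monotone traces, Bayes
consistency at scale) rather than its comparative advantage on real data.
In particular, on this family the W-CLB exchange is close to test-error
neutral at the default collaboration volume, while S-CLB's accepted moves
never hurt by construction; neither observation transfers automatically to
real datasets in either direction.

## Problem sizes used by the test suite

The suite's simulations are desk-scale by design: stump-oracle and AUROC
oracles use a few hundred random problems of up to 30 instances; the
paired W-CLB comparison uses 50 replicates of `n = 400` training and 1000
test instances at the 10%-Bayes-error setting; S-CLB monotonicity uses 20
seeds at `n = 300`, `S = 5`; Bayes-error recovery trains `S = 5, T = 50`
on 5000 instances. These sizes give Monte-Carlo error well inside the
asserted tolerances while keeping a full run in the order of a minute.

## Known limitations

* Collaboration topology and the internals of the exchange phases follow
  the package's own reconstruction (documented above and kept behind config
  switches); other reconstructions are conceivable.
* S-CLB retrains two ensembles per accepted-or-probed pair, so its cost
  grows as `S^2 * T`; it is the safer but slower scheme.
* Binary labels only; no missing-data handling (rejected at load time), no
  feature preprocessing, uniform ensemble averaging only.

## A worked example

```{r example, eval = FALSE}
d <- gaussian_blobs(synth_spec(n = 400, overlap = 2.56, seed = 1))
m <- train_multimodel(d, S = 4, T = 30, eta = 0.5, mode = "sclb",
                      n_exc = 1, seed = 1)
m$error_trace          # non-increasing over the 6 collaboration pairs
test <- gaussian_blobs(synth_spec(n = 2000, overlap = 2.56, seed = 2))
error_rate(test$y, predict(m, test$x)$label)   # near bayes_error(2.56)
```
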