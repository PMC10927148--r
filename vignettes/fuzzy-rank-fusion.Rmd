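---
title: "Fuzzy-rank decision fusion: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-rank decision fusion: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzfuse)
```

## The fusion model

`fuzzfuse` combines the per-class confidence outputs (softmax
probabilities) of M independently trained classifiers into one decision
per sample, at the decision level only: no features, no retraining, no
access to the models themselves. The pipeline is

1. **Validation.** Every confidence row must be a probability vector
   (nonnegative, summing to 1 within a tolerance).
2. **Rank transform.** Each confidence x becomes a fuzzy rank
   `R(x) = 2(1 − 2^(x−1))`, a re-parameterized Mitscherlich saturation
   curve with `R(0) = 1`, `R(1) = 0`, strictly decreasing, and steepest
   near x = 1. The steep drop near 1 is the point of the transform: two
   models at confidence 0.95 and 0.99 are separated much more strongly in
   rank space than two at 0.05 and 0.09, so confident models dominate the
   aggregate exactly where confidence is most informative. Lower rank is
   better throughout.
3. **Top-k membership.** Per classifier and sample, the k classes with the
   smallest fuzzy ranks (ties broken by class order) form that
   classifier's plausible set.
4. **Penalized aggregation.** The fuzzy rank sum FRS adds each class's
   rank across classifiers, substituting the penalty `P_R = 1` (the rank
   of a zero-confidence class) where the class misses a top-k; the
   complemented confidence sum CCFS is one minus the mean of the included
   confidences, with `P_CoF = 0` for missing entries. Both penalties are
   fixed constants of the method, surfaced in the result object but not
   configurable.
5. **Decision.** `FDS = FRS × CCFS`, fused label = argmin over classes.
   A class outside every top-k attains FRS = M and CCFS = 1, hence the
   maximal FDS = M: it can never win.

### The assumptions this encodes

- Base classifiers are roughly comparable in quality and calibrated enough
  that their softmax magnitudes are meaningful; the rule weights models
  implicitly through confidence, never explicitly.
- Errors are at least partly independent across models. When a minority of
  models errs on a sample, the majority's low ranks and high confidences
  pull the fused argmin back to the true class; with strongly correlated
  errors fusion cannot add information.
- Class identity is nominal; nothing ordinal is assumed about the labels.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 2 | top-k cut, 1..C (dimensionless). `k = C` disables penalties; `k = 1` reduces membership to each model's argmax. 2 keeps each model's two plausible classes in play while still penalizing implausible ones — with C = 3 it is the smallest cut that exercises the penalty machinery at all. |
| `variant` | `"complement"` | CCFS reading; see below. |
| `tolerance` | 1e-6 | allowed row-sum deviation from 1. |
| `policy` | `"renormalize"` | rows off by more than the tolerance are rescaled with a warning; `"strict"` errors instead. Softmax vectors saved at limited precision rarely sum to 1 exactly, so renormalization is the practical default. |

## Numerical and design choices

**The CCFS variant.** Read literally, the flattened aggregation formula
sums the included confidences and averages them. That reading is
internally inconsistent with the rest of the method: with the argmin rule
and `P_CoF = 0`, a class with zero confidence everywhere would score
FDS = 0 and always win, and for a single model the literal
`FDS = R(x)·x` is minimized at small x — the *least* likely class. The
complement reading `CCFS = 1 − mean(included CoF)` makes the penalty
rationale coherent (a fully excluded class gets CCFS = 1 and FDS = M, the
worst possible score) and makes single-model fusion with `k = C` reduce
exactly to that model's argmax, since `R(x)(1 − x)` is strictly
decreasing. The package defaults to the complement reading and keeps the
literal one behind `variant = "literal"` purely for auditability; a unit
test pins down the pathological literal behaviour.

**Ties.** Equal fuzzy ranks within a classifier and equal FDS values
across classes are both resolved by class position (first listed wins).
Any rule works; a deterministic, order-stable one makes runs reproducible
and is what the tests rely on. Ties have measure zero for continuous
scores.

**Out-of-range confidences.** Values outside [0, 1] by at most 1e-9 are
clamped (floating-point softmax routinely overshoots by ulps); anything
further is a hard error carrying the sample and class coordinates.

**Degenerate inputs.** Zero-sum confidence rows, negative entries,
misaligned sample ids or class headers, and C < 2 are all rejected at
validation with named offenders. An empty score matrix passes through the
rank transform vacuously.

**ROC scores for the fused decision.** FDS is a loss; one-vs-rest AUC
needs a higher-is-better score. The package uses
`s_c = (M − FDS_c) / Σ(M − FDS_c)`. Any strictly decreasing map of FDS
gives the same AUC (an invariance the tests assert), so this choice only
fixes a convention, not a result.

**Display rounding.** Reported metrics round half away from zero to 4
decimals (`round_half_up()`): base R's banker's rounding would display a
macro recall of 0.92945 as 0.9294 where the conventional table value is
0.9295. Aggregation is macro (unweighted mean over classes) for headline
numbers, with support-weighted values reported alongside; the two are
never mixed in one table.

**McNemar's test.** The discordant counts b and c are compared with an
exact doubled binomial tail (clamped at 1) when b + c < 25 and with the
continuity-corrected χ² `(|b−c|−1)²/(b+c)` otherwise; the regimes agree to
within 0.02 at the boundary, which a property test checks. b + c = 0 is
reported as degenerate with p = 1 rather than an error.

## The synthetic score generator

`simulate_bank()` exists so that fusion, baselines and evaluation are
testable without any trained CNN or image download. Its stated world:
truth labels drawn from configurable class proportions (default
120/561/416 normalized — the imbalanced three-class chest-CT support
pattern); per sample and model a Bernoulli draw at the model's nominal
accuracy decides whether the Dirichlet confidence row is sharpened toward
the true class or toward a wrong one; defaults use three models with
accuracies 0.9902/0.9726/0.9945, the measured accuracies of the three
transfer-learned base CNNs the default setting emulates. Sharpening adds
`concentration` (default 10) to the target class's unit Dirichlet
parameter; 10 was chosen once because it makes the row's argmax recover
the sharpened target with probability ≈ `1 − (C−1)·2^{−(1+conc)}` ≈ 0.999
at C = 3, so empirical accuracy tracks nominal accuracy, while still
producing soft, realistic probability vectors rather than one-hots. With
`error_correlation` ρ > 0 a sample is flagged with probability ρ and
pre-draws one common wrong target that all erring models aim at,
emulating images that are confusing in the same way for every model.

What it deliberately does *not* emulate: the calibration quirks of
specific architectures (temperature, overconfidence), feature-level
correlation between models beyond the shared wrong target, and any image
structure. A green simulation test therefore establishes that the fusion
arithmetic behaves as specified under controlled error structure — not
that any published accuracy on a real dataset is reproduced. Published
headline accuracies depend on trained networks and external image sets
and are out of desk-scale reach; the evaluation tests instead verify that
the metric aggregation reproduces published overall cells exactly from
their per-class values and supports.

## Known limitations

- `k` must be chosen by the user; nothing in the method selects it, and
  the default 2 is a convention, not an optimum.
- The fuzzy-rank rule applies no per-classifier weights; a clearly weaker
  model contributes as much structure as a strong one (only its
  confidences differ). The accuracy-weighted average baseline is the
  comparison point for that idea.
- The literal CCFS variant is provided for audit but is not a sensible
  decision rule; see above.
- With heavily correlated errors (`error_correlation` near 1) fusion
  cannot exceed the base accuracy, and the simulation tests do not claim
  otherwise.
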