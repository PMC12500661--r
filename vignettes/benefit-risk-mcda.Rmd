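---
title: "Benefit-risk MCDA: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benefit-risk MCDA: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brmcda)
```

## The decision model

`brmcda` implements an additive multi-criteria value model for comparing
two treatment alternatives. A two-level value tree splits the total
weight between a *benefit* and a *risk* category (the shipped case study
uses 0.75/0.25, elicited by expert consultation) and, within each
category, assigns each criterion a swing weight on a ratio scale: the
most important criterion gets 100 and the others are scaled against it.
Hierarchical normalization turns these into relative weights

$$\omega_j = w_c \cdot \frac{s_j}{\sum_{k \in c} s_k},$$

which sum to 1 over the whole tree. For the case study this gives
20/15/15/25% for the four benefit criteria and 25% for the single risk
criterion.

Raw pooled outcomes are mapped onto a common 0–100 preference scale by
linear partial value functions between a *worst* and an *optimal* anchor:
rising for benefits, falling for risks, so that for a risk criterion a
*higher* preference means *safer*. Because both functions are affine,
the total score

$$U_i = \sum_j \omega_j U_{ij}$$

is affine in every raw effect value within the anchor ranges — the
property the Monte Carlo stage's convergence check rests on. The total
is a weighted *sum* of the benefit and risk scores, not a difference:
the risk scale is already reversed, and only the sum reproduces the case
study's published totals (0.75 × 72.27 + 0.25 × 56 = 68.2).

## Evidence pooling

Each (criterion, arm) cell is pooled separately: the model consumes
per-arm combined results (mean change for continuous outcomes, incidence
rate for binary ones), not a between-arm contrast. Contrast-level
pooling is the more standard meta-analytic object, but per-arm pooling is
what the scoring stage needs, since each arm is scored on the absolute
preference scale; this choice is deliberate and documented here.

Continuous outcomes use inverse-variance weights $1/(sd^2/n + \tau^2)$;
binary outcomes are pooled directly on the proportion scale so the result
is itself an incidence rate in $[0, 1]$. The between-study variance
$\tau^2$ is the DerSimonian–Laird moment estimator; Cochran's $Q$ and
Higgins $I^2$ are computed against the fixed-effect fit. The phrase
"select the most appropriate model" is made explicit as a policy: fixed
effect when $I^2 \le 50\%$, random effects otherwise, overridable with
`model = "fixed"` or `"random"`. All intervals are normal-approximation
95% intervals ($z = 1.959964$); a single binary study instead gets a
Wilson score interval, which behaves at the 0/1 boundary where the normal
interval degenerates. Boundary proportions receive a shrunken value
$(x + 0.5)/(n + 1)$ in their *variance* only, so their estimate stays
exact while their weight stays finite.

## Scoring: sign convention and clamping

The case study's pooled KPS change is printed as a negative value while
its anchors (2, 11) are positive; only anchoring the *magnitude* of the
change reproduces the published preference values (82 and 18). Scoring
therefore applies an orientation transform declared per criterion
(`magnitude: true` in the config) rather than guessing from signs.

The partial value function is defined only on the anchored range, so
values outside $[\mathit{worst}, \mathit{optimal}]$ are clamped to the
boundary (preference 0 or 100) with a warning. The Monte Carlo stage
inherits the same policy but counts clamped draws instead of warning per
sample; distributions are deliberately *not* truncated, so the clamp is
visible in the output (`n_clamped`) rather than hidden in the sampler.

Preferences are kept at full precision internally. Display rounding is
half-away-from-zero to integers (`round_half_up()`), matching the
convention of the published scoring table; every comparison, ranking and
difference is computed before rounding.

## What reproduces and what does not

`reproduction_report()` recomputes every cell of the case study from its
published anchors, swing weights and pooled estimates. The KPS and
gastrointestinal preference values reproduce exactly (82/18 and 56/24),
as do the experimental benefit value (72), both totals (68/27) and their
difference (41) when the published preference table feeds aggregation.
Three preference cells do **not** follow from the published inputs —
CA211 (printed 67, recomputes to 66.0), CEA (printed 75, recomputes to
66.0) and fatigue (printed 66, recomputes to 81.0) — and the control
benefit value recomputes to 28.4 where 29 was printed (plausibly
intermediate rounding in the original software; unknowable from the
published record). The package reports its computed values and flags the
divergences; it never reconciles them silently. For the same reason the
fixture pipeline aggregates the *published* preference table (provenance
`"asserted"`), while computed preferences are always available via
`score_alternatives()`.

The published Monte Carlo interval for the total difference,
(−16.59, 38.73), does not contain the published mean difference of 41 and
cannot be an equal-tailed interval of the same quantity, and the
published superiority probability of 81.83% is likewise not recoverable
from any stated inputs (with the computed difference distribution,
superiority is near-certain). The Monte Carlo stage is therefore
validated by its statistical properties — seed determinism, agreement of
the Monte Carlo mean with the affine-model value at the triangular means,
a calibrated sampler, and a symmetric-input probability of 0.5 — rather
than against those two printed numbers.

## Sensitivity analysis

`perturb_weight()` scales one weight by $1 + \delta$ (relative mode, the
convention of interactive MCDA software) or shifts it additively
(absolute mode); both are exposed because "a 20% change in weight" is
ambiguous between them. Category perturbations renormalize the sibling
category to keep the top-level weights summing to 1; criterion
perturbations leave sibling swings untouched, which spreads the change
proportionally across siblings after normalization. If scaling pushes a
swing above 100, the whole category is rescaled so its maximum is 100 — a
pure change of scale with no effect on any normalized weight.

For two alternatives the total score is affine in any scanned weight, so
the rank-reversal point solves a linear equation (`crossover_weight()`);
a 0.001-step grid scan backs this analytically in the tests. In the case
study the experimental arm's preference exceeds the control's on every
criterion, so no weight perturbation of any size can reverse the ranking
— the ±20% stability result is a consequence of dominance, and the test
suite checks both the ±20% sweep and the dominance argument itself.

## Monte Carlo uncertainty propagation

Each pooled effect is represented as a triangular distribution with the
95% CI bounds as support and the point estimate as mode — the natural
three-point mapping of an interval estimate, chosen once and documented
here since interval-to-distribution mappings are conventions, not facts.
All (arm × criterion) effects are sampled independently; no correlation
structure is available from arm-level summaries, and none is invented.
Draws go through the same scoring and aggregation code path as point
estimates (vectorized over iterations), and per-iteration benefit, risk
and total differences (experimental − control) are recorded. Interval
estimates are equal-tailed percentile intervals, not normal
approximations; the superiority probability is the fraction of
iterations with a positive total difference. A single seeded generator
drives the run and the seed is recorded in every result and manifest;
identical (model, `n_iter`, `seed`) reproduce the arrays bit-identically.
The default `n_iter = 10000` keeps the Monte Carlo standard error of the
total-difference mean below 0.05 preference points for the case study.

## The synthetic-trial generator

`trial_scenario()` describes what the analysis assumes the evidence base
looks like: $k$ two-arm RCTs (default 6) with 20–45 patients per arm,
per-study true effects drawn around a common mean (between-study SD
`tau`, default 0, applied on the outcome scale for continuous criteria
and on the log-odds scale for binary ones), continuous outcomes reported
as the sample mean and SD of normal change scores, binary outcomes as
binomial counts, and partial outcome reporting following the case study's
observed pattern (four studies report KPS; two each report the tumor
markers, fatigue and the gastrointestinal outcome). The default true
effects sit at the case study's pooled point estimates, with within-arm
SDs (8, 2, 3.5, 9 outcome units) chosen as clinically plausible spreads
consistent with the width of the pooled intervals.

What the generator does *not* emulate: correlated outcomes within a
study, change-score versus endpoint ambiguity, selective reporting that
depends on results, non-normal outcome distributions, and risk-of-bias
features of real trials. Passing tests therefore demonstrate that the
pipeline is statistically sound under its own assumptions — 93–97%
empirical CI coverage at `tau = 0` over 1000 replicates, and the
calibrated scenario ranking the experimental arm first in ≥ 99% of 500
end-to-end replicates — not that the published case study's evidence base
is free of such problems.

## Numerical choices and degenerate inputs

* Weight vectors must sum to 1 within 1e-12 after normalization; the
  top-level weights within 1e-8 at input.
* Ties in ranking are broken by benefit value, then lexicographic id, and
  flagged (`tied = TRUE`) rather than hidden.
* A degenerate triangular spec (all three parameters equal) is a point
  mass, not an error, so fixture runs with zero-width intervals work.
* Identical alternatives make every weight a crossover;
  `crossover_weight()` reports `degenerate = TRUE` instead of an
  arbitrary number.
* Validation of trial summaries collects *all* violations
  (`validate_inputs()`), failing fast only when the pipeline is actually
  run.

## Known limitations

* Exactly two levels of hierarchy and, for crossover analysis and Monte
  Carlo differences, exactly two alternatives; sweeps and scorecards
  handle any number of alternatives.
* Linear partial value functions only — no exponential or piecewise
  utility shapes.
* Binary evidence is pooled as an incidence rate; no odds-ratio or
  risk-ratio pooling, no publication-bias diagnostics, no subgroup
  meta-analysis.
* Probabilistic weight sensitivity (SMAA-style rank acceptability) is a
  natural extension point but is not implemented.
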