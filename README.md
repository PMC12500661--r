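# brmcda

Quantitative benefit-risk assessment of competing treatment regimens by
multi-criteria decision analysis (MCDA), for analysts who need to turn
arm-level randomized-trial evidence into a transparent, weighted,
uncertainty-aware comparison of two alternatives.

The package implements the full pipeline:

1. **Evidence pooling** — inverse-variance meta-analysis of per-study,
   per-arm summaries: mean differences for continuous outcomes, incidence
   rates (pooled proportions) for binary ones, with Cochran *Q*,
   Higgins *I²* and the DerSimonian–Laird between-study variance, and an
   explicit model policy (fixed effect when *I²* ≤ 50%, random effects
   otherwise, overridable).
2. **Scoring** — linear partial value (single-attribute utility)
   functions map each pooled outcome *U* onto a 0–100 preference scale
   between a worst and an optimal anchor:
   *U*<sub>benefit</sub> = (*U* − *U*<sub>min</sub>)/(*U*<sub>max</sub> − *U*<sub>min</sub>) × 100,
   *U*<sub>risk</sub> = (*U*<sub>max</sub> − *U*)/(*U*<sub>max</sub> − *U*<sub>min</sub>) × 100.
3. **Aggregation** — the additive value model
   *U<sub>i</sub>* = Σ<sub>j</sub> ω<sub>j</sub> *U<sub>ij</sub>*, with
   swing weights normalized hierarchically (category weight × swing /
   category swing total) into relative weights ω<sub>j</sub> that sum
   to 1, yielding benefit, risk and total benefit-risk scores and a
   ranking.
4. **Sensitivity** — ±20% (or any) perturbation of every criterion and
   category weight, rank-reversal detection, and analytic crossover
   weights for two-alternative models.
5. **Uncertainty** — Monte Carlo propagation: every pooled effect is
   drawn from a triangular distribution (95% CI bounds as min/max, point
   estimate as mode), scored and aggregated per iteration, giving
   percentile intervals for the benefit/risk/total score differences and
   the probability that one alternative is superior.

A synthetic-trial generator (`trial_scenario()`, `generate_trials()`)
emulates the structure of the evidence base — six small two-arm RCTs with
partial outcome reporting — so the whole pipeline is testable end to end
without any external data.

## Worked example: the NSCLC case study

The package ships a published case study: chemotherapy alone (control)
versus chemotherapy plus an adjuvant herbal decoction (experimental) in
non-small cell lung cancer, with five criteria — KPS score change, CA211
and CEA reduction, Cancer Fatigue Scale change (benefits, category weight
0.75) and gastrointestinal adverse-reaction incidence (risk, 0.25).

```r
library(brmcda)
run <- run_benefit_risk(use_fixture = TRUE, seed = 1)
print(run)
```

```
Benefit-risk MCDA run
Scorecards:
  alternative benefit risk total display
 experimental   72.27   56  68.2      68
      control   28.40   24  27.3      27
Top-ranked: experimental (difference to next: 40.90, displays 41)
Sensitivity: 0/14 perturbations change the ranking
```

The combination arm scores a total benefit-risk value of 68.2 (displays
68) against 27.3 (displays 27) for chemotherapy alone — a difference of
40.9 (displays 41) — and no ±20% weight perturbation reverses the
ranking, because the experimental arm dominates on every criterion.
`run$reproduction` compares every computed cell against the published
scoring table and flags the cells that cannot be recovered from the
published anchors and pooled estimates (the CA211/CEA/fatigue preferences
and the control benefit value, which recomputes to 28.4 where 29 was
printed); see the methods vignette for the full account.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/brmcda.R run-all --fixture --out results/
Rscript inst/cli/brmcda.R simulate --seed 7 --out trials.csv
Rscript inst/cli/brmcda.R run-all --config inst/extdata/nsclc_value_tree.yaml \
    --trials trials.csv --out results/
```

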