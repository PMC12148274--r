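---
title: "Counterfactual evaluation of VTE prophylaxis strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual evaluation of VTE prophylaxis strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vteprophy)
```

## The problem

Pharmacological prophylaxis (low-dose heparin, LMWH or fondaparinux) reduces
the risk of venous thromboembolism (VTE) in medical inpatients but increases
the risk of major bleeding. Randomised trials put the relative VTE reduction
at roughly 27-52% and the relative bleeding increase at roughly 37-92%.
Guidelines therefore recommend weighing both risks when deciding whom to
treat, either with point scores (Padua for VTE, IMPROVE for bleeding) or
with logistic prediction models that output probabilities directly.

`vteprophy` estimates, for a cohort with per-patient predicted risks, what
each candidate prescribing policy would do: how many patients it treats, how
many VTE and bleeding events it is expected to produce, and how efficiently
additional treatment buys additional event reduction. Everything is
counterfactual arithmetic over predicted probabilities; no outcome data are
needed or used.

## The model

Each patient $i$ carries a predicted 14-day VTE probability $p^V_i$ and an
in-hospital major-bleeding probability $p^B_i$, both stored as fractions in
$(0,1)$. A strategy maps patient features to a treatment indication $t_i \in
\{0,1\}$. Under treatment effects $(e, h)$ — efficacy $e$ the relative VTE
reduction and harm $h$ the bleeding multiplier — adjusted risks are

$$\tilde p^V_i = p^V_i\,(1 - e\,t_i), \qquad
  \tilde p^B_i = \min(p^B_i\,h^{t_i},\, 1).$$

The same $(e,h)$ applies to every patient (no effect heterogeneity), VTE and
bleeding are treated as independent non-competing risks, and a VTE and a
major bleed are valued equally. Expected event rates per 1,000 patients are
$1000\,\bar{\tilde p}^V$ and $1000\,\bar{\tilde p}^B$, and the total is
their sum. The cap at 1 matters only for extreme bleeding risks (the
observed maximum, 78.6%, times the maximum harm 1.92 exceeds 1); whether the
original analysis capped is unknowable from the published text, but an
expectation cannot exceed certainty.

Six strategies are implemented (`STRATEGY_NAMES`):

* `no_prophylaxis` — nobody treated; the frontier's reference point.
* `physicians` — the observed prescribing flag.
* `guidelines` — Padua $\ge$ 4 and IMPROVE $<$ 7 (the ASH score rule).
* `cc_minimize_bleeding` — predicted VTE risk $\ge$ 1% and bleeding risk
  $<$ 0.78%.
* `cc_minimize_events` — additionally treats high-bleeding patients whose
  VTE risk outweighs their bleeding risk.
* `near_universal` — everyone with bleeding risk $<$ 0.78%.

Boundary directions (VTE and Padua inclusive, bleeding and IMPROVE
exclusive) follow the published inequality directions exactly.

The phrase "VTE risk outweighed bleeding risk" admits two readings, so
`cc_minimize_events` has a `weighing_mode`: `"expected_events"` (default)
treats when prevented VTEs exceed caused bleeds, $e\,p^V_i > (h-1)\,p^B_i$,
which is the reading consistent with the strategy's goal of minimising total
events; `"raw_risk"` compares $p^V_i > p^B_i$. Ties are not treated. The
mode in force is logged by the command-line runner with every analysis.

## Efficiency frontier and incremental NNT

With $P$ the prophylaxis rate per 100 patients and $E$ the expected total
events per 100 patients (cohort-wide, the only reading under which the
published worked example is coherent), the incremental number needed to
treat between a baseline strategy $S_1$ and a heavier-treating comparator
$S_2$ is

$$\mathrm{NNT} = \frac{P_{S_2} - P_{S_1}}{E_{S_1} - E_{S_2}},$$

e.g. $(50-20)/(1.6-1.3) = 100$ (`nnt_worked_example()`). The efficiency
frontier is the lower convex hull of the $(P, E)$ points, walked from the
least-treating point while $E$ strictly decreases. A strategy strictly above
the hull is *dominated*, covering both direct dominance (another strategy
treats no more and causes fewer events) and extended dominance (a convex
combination of two strategies beats it) — the standard frontier rule in
cost-effectiveness analysis, adopted here because the source analyses label
strategies "dominated" without giving an algorithm. Successive frontier
NNTs are strictly increasing by convexity; the test suite checks the hull
against a brute-force pairwise/segment dominance oracle on random instances.

Numerical choices: hull vertices are found with a monotone-chain scan
dropping collinear points; a point counts as on-frontier when its
coordinates match a vertex within a relative tolerance of $10^{-9}$;
strategies with identical $(P,E)$ collapse onto one frontier point; ties in
$P$ keep the lower $E$ as the hull candidate. Displayed NNTs are rounded to
the nearest 5 above 100 and the nearest integer below (the granularity used
in published tables); machine-readable output keeps full precision.

## Sensitivity grid

`run_grid()` re-runs the whole evaluation over efficacy $\times$ harm
combinations, by default the four corners $\{27\%, 52\%\} \times \{37\%,
92\%\}$ of the published plausible ranges. Within each cell the indications
are **re-derived** under the cell's parameters, because the
minimize-events rule itself references the weighted risk comparison and no
published instruction freezes membership at the base case;
`refresh_indications = FALSE` freezes membership for comparison. Two
consequences worth knowing:

* Higher efficacy (harm fixed) never raises any strategy's VTE rate: it
  shrinks treated VTE risks and can only enlarge the minimize-events
  treated set.
* Higher harm (efficacy fixed) raises treated bleeding risks but also
  shrinks the minimize-events treated set; patients leaving the set revert
  to their lower untreated bleeding risk. Monotonicity of the *cohort*
  bleeding rate is therefore not a theorem for that strategy, though it
  holds comfortably on realistic cohorts (the stayers' increase dwarfs the
  movers' decrease) and is asserted in the tests.

A related subtlety: the treated sets nest as minimize-bleeding $\subseteq$
minimize-events and minimize-bleeding $\subseteq$ near-universal, but
minimize-events $\not\subseteq$ near-universal — minimize-events treats
favorable high-bleeding patients that near-universal excludes. So
near-universal necessarily beats minimize-bleeding on VTE and exceeds it on
bleeding, while its bleeding rate can fall *below* minimize-events' at high
harm (it does on the default synthetic cohort, by ~0.03 events per 1,000),
even though the one published cohort showed the opposite ordering. This is
a property of the joint risk distribution, not a bug.

## The synthetic cohort generator

No patient-level data accompany the published analysis, so
`generate_cohort()` builds cohorts with the statistical structure the
analysis assumes; its defaults are the study conditions:

* **Marginal risks.** Each risk is log-normal, the two-parameter law fully
  determined by the two published statistics via `derive_lognormal_params()`:
  location $\ln(\text{median})$, scale $\sqrt{2\ln(\text{mean}/\text{median})}$.
  Targets: VTE mean 1.26% / median 0.74%, bleeding mean 0.52% / median
  0.21%. Draws are clipped to the observed ranges (0.31-45.3% and
  0.017-78.6%). Clipping leaves the medians untouched and shifts the means
  by under 2% relative; it also places a point mass (~20% of patients) at
  the VTE floor, which mimics a risk model's minimum achievable prediction
  and makes the decile just above the floor empty under
  ties-to-lower-quantile binning.
* **Joint structure.** The log-risks are jointly Gaussian with correlation
  0.3 — no joint distribution is published; a modest positive value reflects
  shared drivers (age, acute illness) of thrombosis and bleeding risk. The
  value is a config field and is swept in the tests.
* **Physician behaviour.** Prescribing is Bernoulli from a logistic model in
  standardised log VTE risk (plus an optional bleeding term, default
  coefficient 0). Intercept and slope are calibrated by weighted least
  squares to three targets: overall rate 61.7% (weight 4; reported to a
  decimal) and bottom/top VTE-decile rates 50%/87% (weight 1 each; read off
  a figure). Calibration errors out if the targets are not ordered
  low < overall < high or the fitted overall rate misses by more than 3
  points. One emergent property: because the risks are correlated and
  prescribing tracks VTE risk, patients in the extreme bleeding tail
  ($p^B \ge 10\%$) are prescribed ~10-15 points *above* the overall rate —
  same direction as the published cohort (66% vs 61.7%) but stronger; the
  decile-level bleeding gradient stays within about ±7 points of flat.
* **Scores.** Padua and IMPROVE item definitions are out of scope, but the
  guidelines strategy needs scores that agree imperfectly with the
  probability thresholds. Each score is a monotone integer transform of the
  normal-score of the corresponding risk rank plus Gaussian noise
  (`score_noise`, default 0.5), cut so that the prevalence of Padua $\ge$ 4
  equals the prevalence of $p^V \ge 1\%$ (likewise IMPROVE $\ge$ 7 and
  $p^B \ge 0.78\%$). At zero noise the threshold crossings coincide; at the
  default the agreement is ~85%, so the guidelines strategy treats a
  similar-sized but genuinely different set than the probability rules —
  consequently its treated-set *size* lands near minimize-bleeding's rather
  than well below it, and the published "guidelines treats fewest" ordering
  is echoed only qualitatively.

What passing tests on these cohorts show: the estimator, frontier and grid
machinery are correct, and the generator hits its calibration targets. What
they cannot show: the published absolute event rates and NNTs, which depend
on the real cohort's joint risk distribution (that is why the published
Table-1-scale numbers are not acceptance targets here).

## Problem sizes and reproducibility

The test suite evaluates the simulation oracle at cohort sizes 10^3 and
10^4 with 10,000 replicates each (agreement within 3 Monte-Carlo standard
errors for all six strategies at all four grid corners), checks the
frontier against brute force on 500 random instances, and calibration
checks run at the full default size n = 46,025, where generation takes
well under a second. All randomness flows through explicit integer seeds;
`generate_cohort()` and `simulate_events()` restore the caller's RNG state.
Generated cohorts carry their seed and a configuration digest in metadata,
written as `#` header comments in every output file, so identically
configured runs are byte-identical.

## A worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(synth_config(seed = 1))
summarize_cohort(cohort)

base <- base_case_analysis(cohort, params = prophylaxis_params(0.52, 1.37))
base$frontier

cells <- run_grid(cohort) # four-corner sensitivity grid
cat(render_table(cells))
```

## Known limitations

* Treatment effects are homogeneous; no subgroup-specific efficacy or harm.
* No competing-risk or within-patient event correlation; totals are sums.
* No event-severity weighting, mortality, heparin-induced
  thrombocytopenia, or costs.
* The generator matches published marginals and prescribing gradients, not
  the unpublished joint distribution of model covariates; orderings that
  hinge on fine joint-distribution detail (e.g. which CC strategy carries
  the most bleeds at high harm) can differ from the real cohort.
* Probabilities are taken as calibrated inputs; miscalibrated prediction
  models would propagate directly into every estimate.
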