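---
title: "Risk-adjusted residuals for identifying impactable high utilizers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-adjusted residuals for identifying impactable high utilizers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

Count-and-cost thresholds find the most expensive members of an insured
population, but many of those members are expensive for clinically
appropriate reasons. `residhu` instead isolates *unexplained* spending:
regress log-scale cost on exogenous factors a payer cannot modify, and treat
the members in the abnormal right tail of the residual distribution as the
candidate "impactable" high utilizers.

The dependent variable is `log10(PMPM)`, per-member per-month expenditure:
total paid over the year divided by months enrolled, log-transformed because
raw costs are strongly right-skewed and the log brings the residuals close
to normality. Members must be 18–60 years old, not pregnant, and have
nonzero spending in the year; the nonzero rule means no epsilon is ever
needed inside the log.

Risk adjustment is ordinary least squares on a one-hot design: an intercept;
one indicator per disease category (diagnosis codes grouped through a
two-column code-to-category mapping, with unmapped codes routed to an
`UNCLASSIFIED` bucket rather than dropped); numeric age; and one-hot blocks
for sex, race, county and plan with one reference level dropped per block.
Correlated covariates are deliberately retained — the coefficients are not
interpreted, only the fit — and only exact collinearity is removed, via the
pivoted solve, with the dropped columns reported. Diagnostics follow the
classical-regression reading of the model: the overall F-test, a normal Q-Q
plot of standardized residuals, and the studentized Breusch–Pagan test
(`n · R²` of the auxiliary regression of squared residuals on the design).

A gradient-boosted tree ensemble is fit to the same design as a
cross-check: squared-error objective with leaf-count (`gamma`) and
leaf-weight (`lambda`) penalties, 1000 trees, learning rate 0.05, with
`max_depth` and `min_child_weight` selected by 5-fold cross-validation
(grids {3, 5, 7} and {10, 50, 200}) on a 60% training split, and R² reported
on the training split, the 40% held-out split, and all rows (the
train-split model scores all rows; no refit). If train and test R² are
similar the ensemble is accepted as not overfit; if its residuals correlate
highly with the linear model's, unmodeled interactions are not what drives
the tail. Trees are built single-threaded with a fixed seed so fits are
bit-reproducible.

## Finding the tail

On the Q-Q plot, the flagged region starts at the smallest standardized
residual from which every larger order statistic exceeds its theoretical
normal quantile by more than `delta` (default 0.1 SD units). Two numerical
choices make this rule robust:

* Theoretical quantiles use plotting positions `(i − 0.5)/n` — symmetric and
  standard.
* The consistency scan ignores the most extreme 0.5% of order statistics
  (`tail_trim`). The extreme order statistics fluctuate on an O(1) scale,
  and standardizing by the sample SD — which the contaminated tail inflates —
  systematically pulls the sample maximum *below* the theoretical extreme
  quantile, so a literal "every order statistic" rule can never latch onto a
  bump-shaped tail. The trimmed points are always part of the flagged
  region; they are only excluded from locating its start.

The implied flagged fraction is clipped into `[min_frac, max_frac]`
(defaults 1% and 7%, the range such a rule selects on claims data), and if
no consistent deviation exists at all — effectively normal residuals, or an
unattainable `delta` — the `max_frac` quantile is returned with a warning.
The alternative `top_fraction` mode takes the `floor(fraction · n)` largest
residuals, ties broken by (residual descending, member id ascending) for
reproducibility; `floor` is the convention under which a 5% cut reproduces
published cohort counts exactly.

Temporal persistence ranks each year's *signed* residuals into average-rank
percentiles and correlates them (Pearson) across year pairs over members
present in both years, dropped pairwise, never imputed. Signed ranking is
deliberate: every downstream use — "do last year's flagged members still
rank high next year?" — treats high percentiles as over-utilization, and an
absolute-value ranking would conflate severe under-utilizers with
over-utilizers. Ranking `|residual|` is available behind the `absolute`
flag for sensitivity analyses.

The code-level breakdown selects a disease cohort by code prefix (e.g. 401
for essential hypertension, 585 for chronic kidney disease, one claim in the
index year suffices), attributes each in-category claim's cost to its
principal diagnosis code as PMPM, orders members by index-year residual into
consecutive groups (configurable size; 5000 at full scale, smaller for
synthetic cohorts), and reports per (group, code) the number of patients and
the group-mean PMPM — members without the code count as zeros, so per-code
means sum exactly to the group's category mean, and the same groups can be
applied to a later year's costs.

Stratified models restrict the cohort to members with nonzero spending in
one setting (inpatient or emergency), rebuild the dependent variable from
that setting's claims only, and keep the covariates unchanged. Their
residuals are compared against potentially-preventable-event records:
group-mean PPR/PPV counts and expenditures with two-sided Mann–Whitney
tests (index year and, where available, the next year, conditioning on
presence), and Pearson correlations between residuals and log10 PMPM event
expenditures. Members with zero event expenditure are excluded from the
log-scale correlation — the log is undefined there — but retained in the
count and mean comparisons.

## What the synthetic generator emulates

`generator_config()` defines the study conditions. Each member carries fixed
demographics (age advances with calendar year), yearly enrollment months and
pregnancy status, and chronic condition categories drawn once from the
configured prevalences. Annual cost follows

```
log10(PMPM) = beta·x + latent_excess + noise,    noise ~ N(0, sigma_noise)
```

with `beta` the true effects (defaults sized so the covariates explain
roughly 55% of log-variance, the share risk adjustment typically reaches on
real claims), and `latent_excess` a two-component mixture: exactly 0 for
most members, and for a planted `excess_fraction` (default 5%) a tight bump
`N(excess_shift, excess_sd)` — by default three noise SDs, SD 0.04 — that
evolves across years as a stationary AR(1) with lag correlation
`persistence_rho` while membership stays fixed. The annual total is split
into claim lines with log-normal weights across the member's condition
categories and independently sampled settings, so claim lines sum to the
member's total by construction. Preventable events are Poisson with
log-link rates `base · exp(ppe_coupling · latent)`; the default coupling
(2.0) gives planted members four-to-five-fold event rates, the order of
contrast published preventable-readmission tables show, and per-event costs
are log-normal with expenditure exactly zero when the count is zero. The
latent truth lives only in a sidecar table, never in the analysis inputs.

Two optional couplings reproduce the code-level variation patterns:
`severity_cost_shift` adds unexplained cost to member-years carrying the
high-severity kidney-disease code (5856), so the high-severity share climbs
across the residual spectrum (a code-mixture gradient); `wcv_coupling`
widens the claim-weight spread of the hypertension category with the latent
excess (within-code cost variance). Both are off in the default
configuration so that the baseline generating model is exactly the additive
equation above; breakdown studies switch `severity_cost_shift = 0.4` on
explicitly. Condition-pair interaction effects (`interactions`) are likewise
available — they are what the boosted trees can capture and the linear model
cannot — and default to none.

Two deliberate consequences of the point-mass-plus-bump design deserve
emphasis, because they bound what passing tests show about real data:

* **Rank-scale persistence does not decay with the year gap by default.**
  Ranks pin the well-separated planted members to the top percentile band,
  so the AR(1) fluctuation (which does decay) contributes almost nothing to
  pooled rank correlations. Decay of the kind real populations show —
  strongest to the adjacent year, weakening with distance — appears when the
  latent is a population-wide mean-zero AR(1) trajectory
  (`excess_fraction = 1, excess_shift = 0, excess_sd = 0.3`); the decay
  validations run under that configuration, and the next-year fade of the
  preventable-event association similarly uses `excess_sd = 0.35`, where the
  exponential rate link amplifies the decaying fluctuation.
* **The generator's settings are split independently** per claim; real
  inpatient and ED costs are dependent within members. Setting-specific
  planted excess is available through `excess_setting`, which scales one
  setting's claim amounts by `10^latent` instead of shifting the total.

Other aspects of real claims the generator does not attempt: realistic
diagnosis-code ontology coverage (a small synthetic code-to-category map
stands in for a clinical grouper, with the real 401x/585x code families kept
for the breakdown analyses), actuarially calibrated cost levels, geographic
structure, and enrollment attrition (every member appears in every year).

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `sigma_noise` | 0.25 | SD of iid log10 noise; all shifts scale against it |
| `excess_fraction` | 0.05 | planted over-utilizer share |
| `excess_shift` | `3·sigma_noise` | planted mean excess, log10 scale |
| `excess_sd` | 0.04 | planted spread; raise toward the shift to study AR(1) dynamics |
| `persistence_rho` | 0.5 | year-to-year AR(1) correlation of the latent |
| `ppe_coupling` | 2.0 | log-link latent-to-event-rate coefficient |
| `delta` | 0.1 | Q-Q consistency tolerance, SD units |
| `min_frac`, `max_frac` | 0.01, 0.07 | clip band for the flagged fraction |
| `tail_trim` | 0.005 | extreme order statistics excluded from the scan |
| `group_size` | 5000 | members per residual group in breakdowns |

## Degenerate inputs and tie-breaks

Zero-cost members are excluded before the log; `months_enrolled < 1`,
non-positive PMPM, empty categories and unknown settings all error with the
violated rule named. A constant response yields R² defined as 0 with zero
slopes; `r_squared()` itself refuses zero-variance inputs. All-tied
residuals still produce exactly `floor(fraction · n)` flags via the
deterministic tie-break, and tied ranks take the mean of their rank range.
Single-level categoricals and constant one-hot columns are dropped from the
design with a message, so the matrix never carries all-zero columns.

## Problem sizes used in validation

The test suite exercises the pipeline at sizes chosen to make Monte-Carlo
bounds sharp while keeping a full run modest: 50,000-member single-year
panels for recovery and decoupling checks (planted-utilizer sensitivity and
precision, AR(1) lag correlation, zero-coupling limits), the default
20,000 × 4-year panel for persistence and model-agreement checks, a
100,000-draw contaminated normal for tail detection, 20-seed replications
for the sign test on correlation decay, and 1000-replicate calibrations for
the Breusch–Pagan and Mann–Whitney type-I rates. `scripts/acceptance.R`
re-runs the same computations from scratch under a caller-supplied seed.

## Known limitations

The method flags *unexplained* spending, not *preventable* spending; the
synthetic preventable-event link is an assumption of the generator, not
evidence about real claims. Residuals inherit every omission of the
covariate set — unmeasured severity, social determinants — and on real data
part of the tail will reflect those omissions rather than impactable
utilization. The boosted-tree model is used only as a robustness check; no
coefficient of either model carries causal meaning. Heteroscedasticity is
reported (Breusch–Pagan) but not corrected beyond the log transform: the
package follows the simple log-scale OLS path throughout, and
heteroscedasticity-consistent standard errors matter only if coefficients
are to be interpreted, which this method never requires.
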