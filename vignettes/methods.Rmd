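---
title: "Model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paapcea)
```

# The decision problem

Incorrect penicillin allergy labels steer prescribing toward second-line
antibiotics, raising costs and harming outcomes. The package models, over
a five-year horizon from the English NHS perspective, whether a
primary-care initiated penicillin allergy assessment pathway (testing and
de-labelling) is worth its up-front cost compared with usual care. The
comparison is informed by the two-arm ALABAMA trial (401 pathway / 410
usual-care participants), whose published parameter table ships with the
package (`table2_params()`).

# Model structure

## Year 1: decision tree

Each arm flows through four chance nodes — receive test, test result,
label removal conditional on the result, treatment failure conditional on
the result-by-label context — into ten terminals. A positive test
(indicating true allergy) never removes the label, so the
positive-and-delabelled pair is structurally zero probability and carries
no payoff; the remaining eight terminals each map to one first-year cost
payoff (GBP, 2022–23 prices) and one annual QALY payoff. Expected year-1
values are exact path-product sums (`enumerate_paths()`,
`expected_year1_payoffs()`), not simulation.

## Years 2–5: extrapolation

Only the 12-month state matters downstream: allergy label status L and
year-1 treatment failure F (untested participants keep their label; no
new failures are generated after year 1). Annual cost in later years is

cost(L, F) = baseline · delabel_mult^(1−L) · tf_mult^F · drift^(t−2),

a Gamma-family log-link regression when fitted from data
(`fit_post_year1_cost_model()`). Annual QALYs are held constant at the
12-month value — no post-12-month quality-of-life data exist to support
anything richer. Year 1 is undiscounted; year t ≥ 2 is weighted
(1+d)^−(t−1) with d = 3.5%/year. This convention is what makes a constant
annual QALY of 0.429 accumulate to 1.577 over years 2–5
(0.429 × `annuity_factor(0.035, 2, 5)` = 0.429 × 3.673080), matching the
published per-period table to rounding.

## Key tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `discount_rate` | 0.035 | /year | UK reference-case rate |
| `horizon_years` | 5 | years | longest follow-up with any trial data (~4.3y) |
| `year1_exposure_fraction` | 1 | — | see "the year-1 scale question" below |
| `baseline` (cost model) | 1500 | GBP/year | magnitude of observed year-2 arm totals (~£1,520–1,537) |
| `delabel_mult` | 0.92 | — | midpoint of the reported 6–11% lower annual costs without a label |
| `tf_mult` | 1.42 | — | midpoint of the reported 39–46% higher annual costs after treatment failure |
| `psa_draws` | 10,000 | draws | Monte-Carlo error on P(cost-effective) ≈ 0.5% |

## The year-1 scale question

The expected year-1 payoffs implied by the published parameter table
(≈ £1,390 and 0.870 QALYs for the pathway arm) are roughly double the
published per-period year-1 values (£684.141 and 0.429). The published
report does not explain the halving, so the model does not hard-code
either behaviour: `year1_exposure_fraction` scales the tree's year-1 cost
and QALY (and hence the constant annual QALY carried forward), with
default 1 (payoffs taken at face value) and 0.5 approximately reproducing
the published per-period scale. Analyses meant to sit on the published
scale should set 0.5 explicitly, as the acceptance script does.

# Uncertainty

Every parameter is a `(family, mean, sd)` triple. Beta and lognormal
parameters are sampled by exact moment matching (round-trip identities are
tested to 10 significant digits); sd = 0 marks a structural constant that
is excluded from probabilistic analysis — this covers the published
table's boundary probabilities (e.g. label removal after a positive test,
fixed at 0) and its substituted payoffs, which are printed with zero SD.
Parameters are drawn independently: the published analysis specifies
per-parameter distributions only, and no correlation structure is
reported. PSA summaries report mean ΔC and ΔQ and count INMB > 0 draws
(ties count as not cost-effective); south-west-quadrant ICERs are
reported as positive "saving per QALY lost" and never averaged with
north-east ratios.

Two readings of the published "SD" column are possible — a sample SD or a
standard error. The package implements both when estimating from data
(`sd_mode = "sample"` / `"se"`), defaulting to the sample-SD reading,
which matches the printed table's magnitudes and reproduces its ~48–52%
cost-effectiveness probabilities; binomial standard errors would be far
smaller than the printed values. One wrinkle: the Bernoulli sample SD
√(p(1−p)) sits exactly on the Beta feasibility boundary, so it is shrunk
by 0.1% when used as a Beta uncertainty SD.

## Missing-branch substitution

Tree branches with no observed members still need payoffs. The published
footnote states the convention for QALYs only (substitute from the
corresponding branch of the other arm); the cost rule is unstated. The
package's default (`resolve_missing_branches()`): QALYs from the other
arm's branch, costs from the same arm's no-test branch matched on
treatment-failure status — a within-arm donor avoids importing the other
arm's testing costs. A fallback chain (other arm, same-arm no-test,
other-arm no-test, pooled mean of populated branches) keeps heavily
stratified analyses (small subgroups, As-Treated reassignment) runnable;
substituted payoffs always enter PSA as fixed, mirroring the printed zero
SDs.

# Relabelling scenario

De-labelled patients may have the allergy label reinstated. The scenario
runs a two-state Markov chain (no-label → label, absorbing) annually over
years 2–5 at a constant rate; a 6-month rate r converts to
1−(1−r)² per year (`annualise_rate()`). On relabelling, costs revert to
the labelled prediction of the cost model. For utilities the published
description gives no rule; the package reverts a relabelled patient's
annual QALY to the *labelled-state mean utility* of their arm (matched on
treatment-failure status). The no-test branch mean was considered and
rejected: with the published payoffs it *exceeds* the de-labelled branch
mean in the pathway arm (0.902 vs 0.880), which would make relabelling
beneficial — the opposite of what the scenario is meant to stress.
Threshold rates for cost saving and for zero net benefit are found by
bisection to 1e-6 (`relabel_thresholds()`), reporting "no crossing in
[0,1]" rather than erroring when a quantity never changes sign.
Probability statements about a literature rate use the monotonicity of
INMB in the rate: P(rate below threshold) = P(INMB at that rate > 0),
draw by draw.

# Value of information

With two strategies, EVPI = E[max(0, b)] − max(0, E[b]) for per-draw
incremental net benefit b. Per-parameter EVPPI uses the positive-part
regression estimator on a polynomial basis (default cubic) — the standard
desk-scale choice; no estimator is named in the published report. EVSI
simulates, conditional on each draw, the summary statistics a follow-on
trial of size n would report (per-arm treatment-failure proportions;
optionally mean cost and QALY differences with sampling noise scaled by
1/√n) and applies the same estimator; it rises toward the informed-set
EVPPI (`evppi_informed()`) as n grows. Trial cost and duration are linear
in n, calibrated through the published (769, £1.76M, 30 months) and
(1267, £2.37M, 46 months) points, which puts the published optimum of 840
participants at £1.85M. Population scaling uses uniform annual cohorts of
total/horizon (79,877 over 10 years by default) discounted at 3.5% with
year 1 undiscounted; the published accrual timing is unstated.

# The synthetic-trial generator

`generate_trial()` emulates the structure the analysis assumes, with the
published parameter table as its default truth: branch membership by the
tree's conditional probabilities; per-branch first-year total costs from
Gamma distributions matched to the configured mean/SD (right-skewed,
non-negative, reproducing the mean ≫ median pattern of the observed
costs) split into service components by the observed cost composition;
utilities from moment-matched Betas in [0,1], constant across years;
later-year costs from the cost-model truth with Gamma noise (CV 2,
matching the observed year-2 dispersion); covariates (age ~ N(54, 16²)
truncated 18–95, 71% female, Poisson comorbidity and antibiotic counts)
drawn independently of outcomes unless an explicit effect is configured —
the published subgroup heterogeneity has no reported joint model, so the
`covariate_effects` option is a stand-in for testing subgroup machinery,
not a claim about the trial. Administrative censoring draws a cut-off
uniformly over a configured window (default days 366–1570, so year-1 data
are complete as in the trial) and scales that year's observed costs to
the exposed days; estimation reverses this by annualising
(× 365 / exposure days).

What passing tests on this generator do **not** show: robustness to
informative censoring, covariate-outcome confounding, within-year utility
trajectories, or any real-data messiness (missingness, linkage error) —
the generator draws exactly from the model's assumed families.

# Numerical choices and degenerate inputs

- Path probabilities are exact products; conservation is asserted at
  1e-12 and against a brute-force enumeration oracle in the tests.
- Zero-cost records in the cost regression are offset by half the
  smallest positive cost; constant-cost data short-circuit to unit
  multipliers.
- Boundary proportions (0/1) become fixed constants; single-member
  branches carry SD 0 and a degenerate flag.
- Sample QALY SDs are capped just inside the Beta feasibility bound.
- Bisection runs at most 100 iterations; exact-zero ties resolve toward
  the lower rate.
- Empty tables, empty arms and empty draws raise explicit errors; failed
  PSA draws are counted and reported, never silently dropped.

# Problem sizes

The test suite exercises parameter recovery at 100,000 participants per
arm (probabilities and payoffs within 3 standard errors) and 50,000 per
arm for the cost-model multipliers (within 5% relative error);
property suites use 1,000 random parameter sets and 10,000-draw PSAs.
The acceptance script runs a 10,000-draw PSA and one full synthetic
re-estimation at the published arm sizes.

# Known limitations

- No mortality, no lifetime horizon, no half-cycle correction beyond the
  year-1 exposure fraction.
- Headline published results cannot be reproduced end-to-end from printed
  inputs alone: the year-1 scale and the exact post-year-1 regressions
  live in unavailable supplementary material. Validation therefore
  combines exact arithmetic identities on the printed tables, structural
  properties, and recovery on synthetic data.
- EVPPI is single-parameter (no Gaussian-process subset emulation); EVSI
  ignores attrition and interim analyses.
- The two published cost-saving probabilities (47.5% and 48%) differ
  between summary locations; both are stochastic summaries and neither is
  treated as exact.
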