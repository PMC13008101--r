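---
title: "Modelling methods: fibrosis screening cost-utility in fibscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling methods: fibrosis screening cost-utility in fibscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibscreen)
```

## The decision problem

Significant liver fibrosis (histological stage F2 or higher) is the main
prognostic marker in MASLD, and adults with metabolic syndrome or obesity
carry most of the risk. Liver biopsy is unusable as a screening test, so
policy interest centres on noninvasive cascades: a cheap blood score
(FIB-4, cutoff ≥ 1.3; or SAFE, cutoff ≥ 0) triaging to transient
elastography (TE, positive at LSM ≥ 7.0 kPa), or TE offered directly.
`fibscreen` evaluates one-time screening at a given age against no
screening, from a societal perspective, in 2023 Thai baht.

## Screening cascade

Tests are abstracted by sensitivity and specificity against true F2–F4
status; individual score computation is out of scope. The decision tree has
leaves: not screened, step-1 negative, step-1 positive not attending TE,
TE negative, TE positive with true F2–F4 (treated true positives), and TE
positive without (treated false positives, who pay for the intervention
without benefit). Step-1 tests and TE are conditionally independent given
true status — published accuracies come from different sources and carry no
joint information, so no correlation can be identified. Leaf masses are
products of uptake rates, prevalence, and test operating characteristics;
a brute-force enumeration of the full outcome tree reproduces every leaf
mass exactly in the test suite.

Each leaf becomes a Markov stratum. Its initial state distribution follows
from Bayes' rule: unconditionally, mass `1 − P(MASLD)` sits in NO_MASLD,
`P(MASLD) − P(F2+)` in F0/F1, and `P(F2+)` in F2/F3/F4-CC; the F0:F1 split
(default 50:50) and F2:F3:F4 split (default 60:25:15) are explicit
assumptions exposed as configuration knobs, because stage-resolved
prevalence within the pools is not available. At ages where the
significant-fibrosis prevalence band exceeds the MASLD prevalence band (the
obesity bands from age 60), the effective MASLD prevalence is clamped up to
the fibrosis prevalence so no pool goes negative; the two band sets come
from different sources and are not mutually consistent at those ages.

## Markov engine

Thirteen states: NO_MASLD, F0–F3, F4/compensated cirrhosis, decompensated
cirrhosis, HCC, transplant (a one-year tunnel), post-transplant, and three
absorbing death states attributed to cardiovascular, liver, or other
causes. Cycles are one year; the cohort runs from the screening age to a
maximum model age of 100 (configurable) — with realistic life tables under
0.1% of the cohort remains alive there, and the terminal row accrues no
further payoff.

Numerical conventions, chosen for bit-for-bit reproducibility:

* **No half-cycle correction.** Each cycle contributes a full year of
  payoff at its starting occupancy; the first cycle is undiscounted
  (`t = 0`).
* **Death competes first.** The per-state annual death probability is the
  life-table probability times a configurable metabolic multiplier
  (default 1) times a hazard ratio: 1.29 for F0–F3, 3.13 for the cirrhotic
  states (F4/CC, DC, HCC), none for NO_MASLD; transplant states instead
  use a flat post-transplant mortality (default 0.05/yr, a documented
  placeholder). Disease exits are scaled by the survivor fraction, so rows
  are feasible by construction; raw exits summing above one raise an error
  naming the row rather than being renormalised silently. The death
  product is capped at 1, which binds only at extreme ages under the
  cirrhotic hazard ratio.
* **Transplant age rule.** DC→LT and HCC→LT are forced to zero once age
  exceeds 70, i.e. entry is permitted while age ≤ 70.
* **Treatment effect.** For treated adherent strata the progression
  probabilities F2→F3, F3→F4/CC and F4/CC→DC are multiplied by `1 − RRR`
  (RRR = 0.204) every cycle for life. Cause-of-death attribution fractions
  (defaults: 0.4/0.4/0.2 CVD/liver/other in cirrhotic states, 0.5/0/0.5
  elsewhere, 0/1/0 post-transplant) do not affect cost or QALY totals and
  are config-overridable placeholders.

Costs per cycle combine annual state costs (a cost-to-charge ratio,
default 1, range 0.6–1.2, applies to the hospital-database-derived states:
baseline metabolic care, F0–F3 and F4/CC), non-medical food and
transportation costs per visit (245.9 THB at tertiary-hospital rates;
default 2 visits/year before decompensation, 4 after — documented
assumptions), and the lifestyle-programme cost for strata that incur it.
Individuals with obesity but no MASLD incur no healthcare and no visit
costs.

**Lifestyle-programme duration.** The programme cost (1,426.8 THB/yr) is
accrued every alive cycle in states NO_MASLD–F4/CC for everyone started on
the intervention, i.e. the programme is lifelong; the evidence base states
a per-year cost with no stop rule. `treatment$lifestyle_duration` caps the
accrual window in years for scenario analysis. This single assumption
dominates the incremental cost: with the default the MetS base case yields
an ICER of ≈ 213k THB/QALY for FIB-4 + TE, whereas setting the duration to
zero makes screening cost-saving — published base-case estimates for this
decision problem (≈ 105k THB/QALY) fall between those poles, consistent
with a shorter programme horizon. We keep the lifelong default because it
is the conservative reading of a per-year cost, and expose the knob rather
than calibrate it.

## Parameters and uncertainty

Every uncertain parameter carries a distribution specification
parameterised by its mean and standard error (the two quantities the
evidence base reports), converted by the method of moments: beta for
probabilities, prevalences and utilities; gamma for costs; uniform over the
stated range for uptake rates that are reported only as ranges. The
treatment effect is sampled on the relative-risk scale — RR = 1 − RRR is
log-normal with matched moments, and the draw is mapped back and truncated
to [0, 1) — because a log-normal on RRR itself would be unbounded above 1
and make the progression multiplier negative. The FIB-4 and SAFE screening
costs are sums of laboratory components, so their standard errors are the
component errors combined in quadrature (39.35 and 44.62 THB).

One-way sweeps bound parameters at mean ± 1.96·SE truncated to the domain
(the "95% confidence interval" reading; distribution quantiles would be the
alternative and can be emulated by editing the bounds), costs at ± 25%, and
range-type parameters (uptakes, adherence 0.60–1.00, cost-to-charge ratio
0.6–1.2, discount rate 0–6%, the two mortality hazard ratios at their
published CIs) at their ranges. The probabilistic analysis samples all
parameters independently — no correlation structure is specified by the
evidence base — with a common draw shared across strategies (standard
practice for incremental comparisons); utilities are sampled without
state-ordering constraints, so occasional non-monotone draws are kept.
Draws whose sampled disease exits are infeasible are deterministically
resampled and counted; more than 5% resampling aborts the analysis. The
CEAC is computed among the three screening strategies only, while the
probability of being cost-effective versus no screening is reported
separately — the two statistics answer different questions.

## Synthetic data and what the tests show

The package ships no third-party data. `synth_life_table()` generates
Gompertz life tables, `q(a) = 1 − exp(−α e^{βa})`; the frozen default
(α = 5.5e-5, β = 0.09) was chosen once to give life expectancy ≈ 77 years
at birth, a plausible national figure, and is used wherever a real life
table is not configured. The repository also ships the same table as a
fixture (`inst/extdata/lifetable_synthetic_thai.tsv`, labelled synthetic).
`toy_scenario()` builds degenerate parameter sets whose discounted QALYs
have closed geometric-series forms, and `microsim_oracle()` re-implements
the engine as an individual-level categorical simulation sharing no matrix
algebra with the cohort path; the suite requires agreement within three
Monte Carlo standard errors at n = 50,000.

Passing tests therefore demonstrate the *mechanics* — tree enumeration,
matrix propagation, discounting, dominance, samplers — not fidelity to any
real population: the synthetic life table has no age-structure quirks, the
auxiliary parameters (visit counts, cause splits, metabolic multiplier,
post-transplant mortality) are documented placeholders, and prevalence
bands are step functions of age. Published base-case results are reproduced
qualitatively in the obesity population (all strategies under the 160,000
THB/QALY threshold, FIB-4 + TE with the lowest ICER and lowest budget
impact) and in the external-validation statistics (life expectancy at 50,
projected MASLD incidence, HCC incidence), but not in the MetS
threshold verdicts, for the lifestyle-duration reason above.

## Scale of the shipped analyses

Deterministic evaluation covers 50 annual cycles (age 50–100) for up to
eight strata per strategy and runs in tens of milliseconds, so the
1,000-draw probabilistic analysis completes in under a minute on one CPU.
The test suite uses 50,000-individual microsimulations for engine
validation and 1,000 random strategy triples for the dominance oracle.

## Known limitations

* No repeated or interval screening; a single screen at one age.
* No HCC from non-cirrhotic states; no tunnel states beyond LT→post-LT.
* Test accuracies are fixed operating points; cutoff choice is metadata.
* The budget impact counts screening-test costs only, with no capacity
  constraints, population growth, or attrition; the national population
  count in the eligible age window defaults to a synthetic 20 million and
  must be configured for real use.
* Parameters are sampled independently in the PSA; joint uncertainty in
  the prevalence bands or between test accuracy and prevalence is not
  modelled.
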