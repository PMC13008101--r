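# fibscreen

Cost-utility and budget-impact modelling of one-time screening for
significant liver fibrosis (stage F2 or higher) in adults with metabolic
syndrome (MetS) or obesity — the populations at highest risk of metabolic
dysfunction-associated steatotic liver disease (MASLD). The package is
aimed at health-economic analysts and hepatology policy researchers who
want a tested, reproducible implementation of this class of screening
evaluation, with every stage runnable offline from synthetic inputs.

## The model

Four strategies are compared from a societal perspective:

* **No screening** — natural history only.
* **FIB-4 + TE** — FIB-4 blood score (cutoff ≥ 1.3) triages to transient
  elastography (TE, positivity LSM ≥ 7.0 kPa); uptakes 90% / 90%.
* **SAFE + TE** — SAFE score (cutoff ≥ 0) triages to TE; uptakes 90% / 90%.
* **TE alone** — one-stage elastography at 80% uptake.

A decision tree partitions the cohort by test outcome using each test's
sensitivity/specificity against true F2–F4 status (tests conditionally
independent given that status). For a two-stage strategy the treated true
positives have mass

```
u1 · π · Se1 · u2 · Se_TE
```

with `π` the age-banded prevalence of significant fibrosis; TE false
positives incur intervention costs without benefit. Each decision-tree leaf
becomes a stratum whose initial distribution over the health states follows
from Bayes' rule.

The Markov engine then runs 13 states — no MASLD, F0–F3, compensated
cirrhosis (F4/CC), decompensated cirrhosis (DC), hepatocellular carcinoma
(HCC), transplant (LT), post-transplant, and three cause-attributed death
states — in 1-year cycles to age 100, with costs and QALYs discounted at 3%
per year. Death competes first: the per-state death probability is the
life-table risk times hazard ratios of 1.29 (non-cirrhotic MASLD) or 3.13
(cirrhotic states); disease transitions apply to the survivor fraction.
Treated adherent true positives have their progression probabilities
(F2→F3, F3→F4/CC, F4/CC→DC) multiplied by `1 − RRR` with RRR = 0.204 from
lifestyle intervention. Downstream modules compute ICERs with simple and
extended dominance (willingness-to-pay 160,000 THB/QALY ≈ 4,619 USD),
tornado-style one-way sweeps, a 1,000-draw probabilistic sensitivity
analysis with CEACs, a threshold search on the TE unit cost, and a 5-year
open-cohort budget impact projection.

## Worked example

```r
library(fibscreen)
p <- default_parameters("mets")   # metabolic syndrome, screening age 50
cost_effectiveness(p)
```

```
Cost-utility analysis (WTP 160000 THB/QALY)
  strategy life_expectancy     cost cost_usd   qaly icer_vs_comparator
 no_screen           26.77 142377.4   4110.2 15.397                 NA
   fib4_te           26.79 144419.3   4169.1 15.406           212735.7
   safe_te           26.79 146270.5   4222.6 15.410           306643.2
  te_alone           26.80 148047.7   4273.9 15.411           394775.7
 frontier_icer       status dominated_by cost_effective
            NA nondominated         <NA>           TRUE
      212735.7 nondominated         <NA>          FALSE
      597624.2 nondominated         <NA>          FALSE
     1065833.9 nondominated         <NA>          FALSE
```

Each row is one strategy: discounted lifetime cost (THB and USD) and QALYs
per person, the ICER against no screening, and the incremental ICER along
the dominance frontier. Under the default parameterisation (synthetic life
table, lifelong lifestyle-programme cost) screening buys a small QALY gain
(≈ 0.01) at 2,000–5,700 THB per person, so no strategy clears the 160,000
THB/QALY threshold in MetS; in the obesity population
(`default_parameters("obesity")`) all three strategies do. The
methods vignette discusses which auxiliary assumptions drive this and how
to change them.

```r
cost_per_true_positive("fib4_te", p)
#>            tests_only           tests_visits tests_visits_lifestyle
#>              17497.58               23500.55               26870.98
```

— the screening outlay per true positive started on treatment, under three
component conventions.

Other entry points: `run_psa()` / `psa_summaries()` (CE plane, probability
cost-effective, CEAC), `one_way_sweep()` (tornado), `threshold_te_cost()`,
`scenario_sweep()` (screening ages 30–80), `compute_budget()` (budget
impact), and `run_command()` — a one-call driver that writes CSVs plus a
run manifest (also exposed as a thin CLI in `inst/cli/fibscreen.R`).

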