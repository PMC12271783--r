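# psptree

A decision-analytic cost-effectiveness engine for emergency-department
management of moderate-to-large **primary spontaneous pneumothorax
(PSP)** in stable adults. Four initial strategies — observation only,
needle aspiration, small-bore chest tube with a one-way valve, and
small-bore chest tube to suction — are compared by expected cost (2022
USD), lifetime discounted quality-adjusted life-years (QALYs), and net
monetary benefit

> NMB = λ·E − C

at a willingness-to-pay threshold λ = $50,000/QALY, with a 3% annual
discount over the remaining lifetime (base case: age 25, life
expectancy 78). The model is a pure decision tree: each strategy
succeeds with its pooled randomized-trial probability or escalates
(failed first-line → chest tube to suction with admission; failed
suction in any pathway → VATS), ending in one of two terminal health
states (resolved with or without surgery). It is aimed at health
economists and emergency/thoracic researchers who want the model, its
sensitivity analyses, and its validation oracle as reusable, testable
code rather than a point-and-click tree.

The package provides:

* exact expected-value **rollback** of the tree (`rollback()`),
  verified against brute-force path enumeration;
* per-strategy **outcomes** and incremental tables
  (`strategy_outcomes()`, `incremental_analysis()`, `rank_by_nmb()`);
* one-way **tornado** analysis over every ranged parameter
  (`tornado_analysis()`);
* **probabilistic sensitivity analysis** by Monte Carlo over
  moment-matched beta/gamma distributions (`run_psa()`), with
  acceptability curves (`ceac()`);
* a patient-level **microsimulation** used as a stochastic oracle
  (`simulate_patients()`) and synthetic trial-count generation
  (`synth_trial_counts()`);
* CSV **report writers** (`run_base_case()`, `run_dsa()`,
  `run_psa_report()`, `run_microsim_report()`) and a thin command-line
  wrapper (`inst/cli/psp_cea.R`).

All inputs live in a declarative YAML configuration; the packaged base
case (`inst/extdata/psp_base_case.yaml`) carries the published
probabilities, CPT/DRG costs, utilities and settings.

## Worked example

```r
library(psptree)

params <- base_case_parameters()
tree   <- build_psp_tree(params)
out    <- strategy_outcomes(tree, params)
out
#> <psp_outcomes> WTP $50,000/QALY
#>           strategy  cost effectiveness     nmb
#>   observation_only  9170         24.90 1235884
#>              valve 14644         24.86 1228113
#>  needle_aspiration 19644         24.79 1219772
#>            suction 52998         24.40 1166820
```

Observation only is cheapest ($9,170 expected: most patients incur only
the ED visit and radiograph) and most effective (fewest patients reach
VATS and its long-term 0.83 utility), so it has the highest NMB; the
one-way valve is the best interventional option; suction is dominated —
its $28,859 admission is certain, not a failure contingency. The NMB
gap between observation and suction is $69,064 per patient. Absolute
effectiveness here is a 53-year discounted utility annuity (~24.9
QALYs); rankings and between-strategy differences, not absolute levels,
are the decision quantities (see the methods vignette on why the
published table's absolute values are not reproducible).

```r
tornado_analysis(params)[1:4, c("parameter", "bar_width")]
#>   parameter bar_width
#> 1   p_valve 19579.566
#> 2      p_na 15741.232
#> 3     p_obs 10367.706
#> 4 p_suction  5776.398

psa <- run_psa(params, n = 5000, seed = 1)
psa$summary[, c("strategy", "p_optimal", "p_least_effective")]
#>            strategy p_optimal p_least_effective
#> 1  observation_only    0.8306                 0
#> 2 needle_aspiration    0.0050                 0
#> 3             valve    0.1644                 0
#> 4           suction    0.0000                 1
```

The tornado (frontier-NMB metric: how far the best strategy leads the
runner-up) is driven by the success probabilities; the PSA confirms
suction as worst in every draw, while observation wins ~83% of draws —
the valve overtakes it when its widely-ranged success probability
(0.53–0.91) draws high.

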