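---
title: "Methods: a decision-tree cost-effectiveness model of pneumothorax management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree cost-effectiveness model of pneumothorax management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psptree)
```

## The decision problem

A previously healthy adult (base case: 25 years old, life expectancy 78
years) presents to the emergency department with a moderate-to-large
primary spontaneous pneumothorax (PSP) and is haemodynamically stable.
Four initial management strategies are compared, in order of increasing
invasiveness:

1. **observation only** — discharge without intervention if no procedure
   is needed at the index visit;
2. **needle aspiration** — percutaneous aspiration of the pleural air;
3. **small-bore chest tube with a one-way valve** — outpatient
   management with the valve in place;
4. **small-bore chest tube to suction** — admission with the tube on
   continuous suction.

Strategies are compared from a US healthcare-system perspective by
expected cost (2022 USD), lifetime discounted quality-adjusted
life-years (QALYs), and net monetary benefit
$\mathrm{NMB} = \lambda E - C$ at a willingness-to-pay threshold of
$\lambda = \$50{,}000$ per QALY. Higher NMB is better; reporting NMB
rather than ICERs keeps multi-way comparisons on a single interpretable
scale.

## Model structure

The model is a pure decision tree (no state-transition cycles): one
decision node over four strategy subtrees of chance and terminal nodes.
Every patient incurs a high-complexity ED evaluation and a chest
radiograph; supplemental oxygen is given but carries no billed cost
line, so it is costed at zero. Each strategy then succeeds with its
pooled randomized-trial probability or fails and escalates:

* failed **needle aspiration** leads to a small-bore chest tube to
  suction with admission (per the source-trial protocols);
* failed **observation** is treated the same way — the escalation after
  failed observation is not specified by the published protocols, so
  the model mirrors the aspiration rule; this is a structural option
  (`psp_structure(observation_failure =)`), and only this variant is
  currently defined;
* a failed **one-way valve** is converted to suction on admission. By
  default no second catheter is billed (the catheter is already in
  place); `valve_failure = "rebill_catheter"` bills a new one;
* **suction failure in any pathway** proceeds to video-assisted
  thoracoscopic surgery (VATS). VATS is never an initial strategy. By
  default the VATS admission DRG is billed *in addition to* the
  pneumothorax admission of the failed-suction stay (a sequential-event
  reading); `vats_billing = "replace"` substitutes it.

Because no conditional estimate is available, the success probability of
rescue suction after a failed first-line intervention is taken equal to
the initial-suction success probability (0.756). Death from PSP is rare
enough to be excluded, so every pathway ends in one of two terminal
states: `resolved_no_vats` or `resolved_post_vats`. The default tree has
11 terminal pathways (3 each for observation/aspiration/valve, 2 for
suction). Terminal payoffs are the service costs summed along the
pathway; `rollback()` computes exact expected values, equal to
probability-weighted path enumeration.

## Inputs

All inputs live in a YAML configuration
(`system.file("extdata", "psp_base_case.yaml", package = "psptree")`);
each carries a base value and a `[low, high]` sensitivity range.

```{r inputs}
parameter_table(base_case_parameters())
```

Units: probabilities and utilities are dimensionless on `[0, 1]`; costs
are 2022 USD (CPT professional+facility fees for ED services, DRG
medians for admissions); the discount rate is per year; age and life
expectancy are years; the WTP threshold is USD per QALY.

## Effectiveness and discounting

The horizon is the remaining lifetime, `life_expectancy - age` (53
years in the base case). QALYs are discounted annually in advance at
rate $r$ (base 3%):
$E(u) = u \sum_{t=0}^{H-1} (1+r)^{-t}$.
All modelled costs fall at the index episode ($t = 0$) and are
therefore undiscounted.

Two utility-trajectory modes are provided:

* **`lifetime`** (default): the terminal-state utility weight applies
  for the entire remaining lifetime. A resolved PSP without surgery is
  worth 0.92, after VATS 0.83 (a long-term intermittent-dyspnoea
  surrogate), for every remaining year.
* **`first_year`**: the terminal-state utility applies in the first
  year only, with the baseline utility (1.0) thereafter — for users who
  read the state utilities as transient.

The published base-case table that motivates this model is not
internally consistent: its absolute effectiveness values cannot be
derived from 3% discounting over the stated horizon under any standard
annuity, and its printed NMB values do not satisfy
$\mathrm{NMB}=\lambda E - C$ for its own printed $E$ and $C$. This
engine therefore makes no attempt to match those absolute values; what
it reproduces, and what the tests check, are the *identities* the
definitions force (NMB linearity, incremental differences) and the
*qualitative* findings (strategy ranking, sensitivity drivers,
probabilistic dominance patterns). With the `lifetime` mode the engine's
absolute NMBs are on the order of $1.2M — a 53-year utility annuity at
$50,000/QALY — while the ranking and the NMB differences between
strategies, which drive the decision, are of the same order as the
published gaps.

## Ranking and incremental analysis

Strategies are ranked by descending NMB; exact ties go to the less
invasive strategy. `incremental_analysis()` reports cost, effectiveness
and NMB differences against a reference strategy, flags simple
dominance (more costly, no more effective) and leaves the ICER
undefined — never computed by division — when the effectiveness
difference is zero. No extended-dominance frontier pruning is done: the
comparison metric is NMB.

## One-way sensitivity analysis

`one_way_dsa()` re-evaluates the *full* model (rebuild, rollback,
outcomes) with one parameter at each end of its range, everything else
at base; `tornado_analysis()` does this for every ranged parameter and
sorts by bar width. No cached intermediate is reused, so the endpoint
values equal fresh evaluations by construction, and a test asserts it.

The outcome metric was a genuinely open design choice, and the obvious
candidate — the NMB of the base-case optimal strategy — turns out to be
the wrong one: parameters of the *competing* strategies (e.g. the
needle-aspiration success probability) have exactly zero effect on the
observation subtree, so a tornado on that metric is blind to the
drivers that matter for the decision. The default metric is therefore
the **frontier NMB**: the NMB of the base-case optimal strategy minus
the best NMB among the alternatives, the quantity whose sign *is* the
decision. On this metric the widest bars in the base case are the
valve, aspiration and observation success probabilities, followed by
the rescue-suction probability and the two long-term utilities —
consistent with the published finding that the resolved-PSP utility and
the aspiration and observation success rates drive the model.
Per-strategy tornados (including the optimal-strategy-only one) remain
available via `metric = "strategy"`.

## Probabilistic sensitivity analysis

The published analysis states that 5,000 Monte Carlo draws were taken
from "estimated distributions" without naming families. The package's
choices, standard for bounded and non-negative quantities:

* probabilities and utilities: **beta**, moment-matched with mean equal
  to the base value and the `(low, high)` range treated as a central
  95% interval, i.e. $\sigma = (\mathrm{high}-\mathrm{low})/(2 \times 1.96)$;
* costs: **gamma**, same moment matching;
* infeasible matches fall back to **uniform** on `(low, high)` — this
  happens for the baseline utility, whose mean 1.0 sits on the beta
  boundary;
* degenerate ranges are **fixed**; settings (discount rate, age, life
  expectancy) are fixed by default because they are scenario choices,
  not epistemic uncertainty (`settings = "uniform"` samples them too).

Parameters are drawn independently: no correlation structure is
published, and inventing one would be harder to defend than none.
Draws are seed-reproducible bit-for-bit; an all-fixed specification
reproduces the deterministic base case exactly, which is tested.

One qualitative published finding reproduces only partially under these
distributions. Suction is the least cost-effective strategy in
essentially 100% of draws, as published. But observation attains the
maximal NMB in roughly 83% of draws rather than "all": the one-way
valve's success-probability range (0.53–0.91, hence a sampling standard
deviation near 0.10) is wide enough that the valve draw exceeds the
observation draw by the ~0.10 needed to overtake it in a sizeable
minority of simulations. Reproducing full dominance would require
materially tighter distributions than the printed ranges imply (for
example betas parameterised by the underlying trial counts, which are
not published for the pooled estimates); the package deliberately does
not assume them. The acceptance suite records this check against the
published "all simulations" claim as failing, by design.

The cost-effectiveness acceptability curve (`ceac()`) recomputes each
draw's NMB over a WTP grid (default $0–$200,000 in $5,000 steps) and
reports maximal-NMB frequencies; at the default threshold the curve
point equals the PSA summary.

## Microsimulation oracle and synthetic trial counts

`simulate_patients()` routes individual patients through a strategy
subtree with independent draws at every chance node. It exists as a
brute-force cross-check of the analytic rollback: cohort mean cost and
terminal-state frequencies converge at $\sim 1/\sqrt{n}$, and the test
suite compares them at $n$ up to $10^5$ within three standard errors,
plus a goodness-of-fit test on the terminal-state counts. Per-patient
stored costs are re-derivable exactly via `path_cost()`.

`synth_trial_counts()` emulates a randomized-trial arm (binomial
successes at a true proportion, 95% Wilson score interval — chosen
because it behaves well at the source-trial sizes); at the pooled
observation-trial conditions (p = 0.846, n = 162) the expected count is
137.05, emulating the published 137/162. What the generator emulates is
sampling noise around the pooled estimates; it does not emulate
between-trial heterogeneity, arm correlation, or how the pooled values
were derived from the 15 source trials (taken as given), so passing
tests show engine correctness under the stated inputs, not robustness
of the inputs themselves.

## Numerical choices

* Chance-node branch probabilities must sum to 1 within `1e-12`;
  complementary success/failure branches satisfy this exactly.
* Rollback vs enumeration agreement is asserted at `1e-9` relative
  tolerance; terminal-state distributions sum to 1 within `1e-12`.
* Degenerate probabilities (0 or 1) are valid branch weights; a
  strategy with success probability 1 collapses exactly to its success
  pathway.
* NMB ties break toward the less invasive strategy everywhere a single
  winner is needed (ranking, PSA win counting, CEAC).
* Reports round dollars to the nearest integer and QALYs to two
  decimals; all internal arithmetic is full double precision.
* Each stochastic operation (`sample_parameters()`, `run_psa()`,
  `simulate_patients()`, `synth_trial_counts()`) runs its own
  explicitly seeded RNG stream and restores the caller's RNG state.

Problem sizes used by the packaged checks — 5,000 PSA draws, $10^5$
microsimulated patients, 1,000 random trees for the rollback property —
are the package's own verification choices, matching the published
simulation count where one exists.

## Limitations

* Complication costs are not modelled (complication risk enters only
  through the post-VATS disutility), and follow-up costs beyond the
  index episode are out of scope.
* The observation strategy's "success" (safe discharge without
  intervention) is a different endpoint from radiographic resolution;
  the model inherits that asymmetry from the source trials.
* The two-state terminal space cannot represent recurrence, and the
  tree has no time dimension beyond the discounting horizon.
* PSA distribution families, independence, and the central-95% reading
  of the ranges are this package's assumptions, not published facts.
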