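---
title: "Setting non-inferiority margins with a cohort decision model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Setting non-inferiority margins with a cohort decision model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nimargin)
```

## The problem

A de-escalation trial asks whether a lighter intervention (here: 10-yearly
instead of 5-yearly surveillance colonoscopy after low-risk adenoma removal)
is "not too much worse" than the standard. The non-inferiority margin δ — the
largest tolerable excess in the alternative arm's event rate `p_A` over the
standard arm's `p_S` — is the single most consequential design choice: the
required sample size scales as 1/δ². `nimargin` derives δ from an explicit
trade-off rather than judgement: δ is the tipping point at which the
alternative arm's lower intervention burden exactly offsets its higher
disease rate, measured in lifetime quality-adjusted life-years (QALYs), or in
net monetary benefit (NMB = λ·QALYs − costs) when cost savings should count
too. Defining the margin as *equipoise* (a zero QALY gap, not an "acceptable
loss") is deliberate: any tolerated QALY loss would re-introduce exactly the
arbitrary judgement the method removes.

## The cohort model

Step 1 needs a decision model mapping (exam schedule, event rate over the
trial horizon) to lifetime outcomes. Full natural-history microsimulations of
colorectal cancer serve this role in practice but are not reproducible from
their publications; `nimargin` uses a deliberately reduced deterministic
cohort model whose only contract is that mapping:

* **States.** Alive event-free; diagnosed (indexed by time since diagnosis up
  to a cure horizon); cured; dead of other causes; dead of the disease; dead
  of an exam complication. Monthly cycles by default, from entry age to a
  truncation age of 100.
* **Background mortality.** Gompertz hazard
  `mu(a) = a0 * exp(b (a − 50))`, defaults `a0 = 0.004`/yr, `b = 0.09`/yr,
  or a tabulated annual life table. The defaults give a residual life
  expectancy at 50 of about 29.7 years (the tests verify the annual table
  against direct quadrature of the survival curve).
* **Event hazard.** A baseline diagnosis hazard exponential in age (doubling
  every 12 years, default 0.001/yr at age 50). Only its *shape* matters: a
  scalar multiplier ψ is calibrated by bracketed root finding so the cohort's
  cumulative incidence of diagnosis over the 10-year trial horizon — *in the
  presence of competing mortality*, i.e. the real-world probability of being
  diagnosed — equals any requested `p`. The same ψ keeps acting for the rest
  of life: the simplest lifetime extension of a rate that is only pinned down
  over the horizon. This is a genuine modelling choice (the horizon-to-
  lifetime translation is underdetermined), and it has a visible consequence:
  arms with different schedules need different ψ to hit the same 10-year
  rate, so their life-years differ slightly even at equal horizon
  effectiveness. Orderings and signs are unaffected.
* **Exams.** Scheduled at `start_age + k·interval` up to a stop age (default:
  5-yearly → ages 55–75; 10-yearly → 60 and 70), applied instantaneously to
  alive, not-yet-diagnosed persons. Each exam multiplies the event hazard by
  `1 − ρ·ε` until the next scheduled exam (or for one interval after the
  last), with per-exam protection ρ = 0.5 and a sensitivity multiplier
  ε = 1 by default; ε is the axis on which exam-sensitivity perturbations
  (±5%) are swept. Schedules are fixed by the arm, not adapted to findings —
  the trial randomizes the schedule itself.
* **After diagnosis.** An excess mortality rate (default 0.10/yr) acts for a
  cure horizon (default 5 years); survivors revert to background mortality.
  The defaults imply that roughly 40% of diagnosed patients die of the
  disease, the magnitude of colorectal-cancer survival.

Person-time uses a half-cycle correction throughout, including a half-cycle
credit to the diagnosed state in the cycle of diagnosis (without it, high
event rates leak person-time at the healthy→diagnosed hand-off). State
occupancy is conserved to 1e−12 per cycle, and calibration achieves the
target incidence to better than 1e−6 (both asserted in the tests).

## QALY and cost accounting

Per 1000 entering patients, lifetime:

| parameter | default | unit | source of the default |
|---|---|---|---|
| anxiety before an exam | 21 days at decrement 0.1 | QALY-days | stated burden decomposition |
| preparation + procedure | 2 days at decrement 0.5 | QALY-days | stated burden decomposition |
| per-exam disutility | 3.1 (= 21·0.1 + 2·0.5) | days | derived |
| disutility scaling | 1.0 (0.8/1.2 alternates) | – | population-percentile factor |
| complication risk | 0.002 at 40 → 0.038 at 85 | per polypectomy exam | exponential between anchors |
| complication loss | 14 | days | two weeks per complication |
| fatal complication | 1/30,000 | per polypectomy exam | stated |
| polypectomy fraction | 0.3 | – | not stated anywhere; explicit knob |
| disease disutility | 0.30 / 0.10 / 0.45 | initial / continuing / terminal phase | synthetic placeholders |
| unit costs | 885 / 10,000 / 25,000 / 2,500 / 30,000 | EUR; exam / complication / phase-years | synthetic placeholders |
| willingness-to-pay λ | 20,000 | EUR per QALY | conventional threshold |

`QALYs = life-years − surveillance losses − complication losses − treatment
losses` holds to 1e−9 by construction and is re-asserted on every scenario.
Days convert to years with 365.25. Complication *deaths* are applied inside
the cohort (a per-exam fatal risk = polypectomy fraction × fatal
probability), so their life-year cost emerges from the trace rather than
being added post hoc. Terminal-phase person-time is booked as
min(time since diagnosis, 1 year) per disease death and deducted from the
initial/continuing time it overlaps — an expectation-level approximation that
is exact in aggregate, chosen because a forward cohort recursion cannot
attribute "the last year of life" retrospectively. The disease-phase
disutilities and all unit costs are placeholders (their published sources do
not print values), so every test touching them is property-based (orderings,
identities, homogeneity), never value-based; analyses using the defaults
should be read the same way.

Discounting is supported (continuous, per-cycle weights) but off by default,
matching undiscounted published totals.

## Solving for the margin

The QALY gap `ΔQALY(p_A)` (alternative − standard, standard fixed at `p_S`)
is strictly decreasing in `p_A` (verified on a 50-point grid). The solver
brackets the root starting from `[p_S, p_S + 0.01]`, doubling the width up to
`p_A = 0.2`, then applies Brent's method with a bisection fallback. The
stopping rule is on the *gap* (default 1e−4 QALYs per 1000), not on `p_A`,
because the gap's slope varies by scenario; the NMB solver multiplies that
tolerance by λ so the two criteria stop at comparable precision. Degenerate
cases are explicit errors: a negative gap at `p_S` ("never non-inferior") and
a positive gap at the bracket ceiling ("dominates at all plausible rates").
Equal QALYs at `p_S` (e.g. zero burden and no protection) return δ = 0.

Calibration inside each gap evaluation is warm-started from the previous
evaluation (a proportional fixed-point iteration on ψ, falling back to
bracketed root finding) and solved to 1e−12 in incidence, keeping the gap
function smooth enough for tight solver tolerances; the tests check the
solver against a 10,001-point grid scan of the gap on 20 randomized scenarios
and against closed-form linear ("two-period") scenarios to 1e−8. The core is
fully deterministic, so identical configurations reproduce bit-identical
results; the only randomness in the package is the power simulation, which
takes an explicit seed and restores the global RNG state.

## Trial sizing and power

`required_sample_size()` uses the unpooled normal-approximation formula (see
README) with normal quantiles rounded to 3 decimals (1.645, 1.282) by
default — the convention under which the familiar published sizes (19,234;
8,826; 16,754 at δ = 0.42%, 0.62%, 0.45%) reproduce exactly; full-precision
quantiles move the sizes by ≤ 5 per arm (asserted). The assumed true `p_A`
defaults to `p_S` (equal true efficacy), the only assumption under which
those sizes arise. `simulate_power()` draws binomial counts per arm and
applies the matching one-sided unpooled Wald test; the tests require
agreement with the closed-form power within 3 Monte-Carlo standard errors at
five design points and correct size on the null boundary.

## What the default scenario does and does not emulate

It emulates: two fixed surveillance schedules in a middle-aged cohort,
competing mortality, a calibrated 10-year event rate, age-increasing
exam-complication risk, per-exam disutility, post-diagnosis excess mortality
and a per-exam protective effect. It does *not* emulate adenoma-level natural
history, cancer staging, findings-dependent surveillance intervals, utility
heterogeneity beyond a scalar percentile factor, or dropout. Consequently,
absolute outputs (life-years, QALY totals, the 0.34% default margin) are
model-specific and differ from figures produced by calibrated
microsimulations; the quantities the package reproduces exactly are the
burden decomposition, the complication-model anchors, the sample-size
arithmetic and the power, and the quantities it reproduces structurally are
the orderings — wider margins (smaller trials) for higher assumed burden, and
wider margins under the cost-effectiveness criterion whenever the lighter arm
is also cheaper. Passing tests therefore certify the machinery and those
orderings, not clinical values for a real trial.

## Numerical and test-design choices

* Monthly cycles for headline analyses (smooth enough for root finding on
  `p_A`); the randomized many-evaluation property suites run at quarterly
  cycles, where the solver-vs-grid agreement they certify is unchanged and
  the 20-scenario × 10,001-point scan stays inexpensive.
* Cycle length must divide one year and all exam-age offsets; misalignment is
  an error, not a silent rounding.
* Calibration: incidence tolerance 1e−12; targets outside the achievable
  range report that range. `target = 0` short-circuits to ψ = 0.
* Sweep grid points are solved independently (order-invariant, failures
  recorded per row with a status code); the conservative recommendation is
  reported as the maximum total sample size over the grid, not applied as a
  decision rule.
* Sample sizes use `ceiling()` with a 1e−9 guard against floating-point
  landings exactly on integers.

## Limitations

The post-horizon constant-multiplier extension and the placeholder
disutilities/costs are the two assumptions most likely to move absolute
margins; both are single parameters exposed in the configuration, so
one-way sweeps over them are the recommended reading of any absolute number
this package produces.
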