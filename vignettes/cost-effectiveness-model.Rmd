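---
title: "A half-cycle-corrected Markov cohort model for adjuvant HER2-positive breast-cancer regimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A half-cycle-corrected Markov cohort model for adjuvant HER2-positive breast-cancer regimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The model

`markovcea` implements a four-state Markov cohort model for comparing two
trastuzumab-containing adjuvant chemotherapy strategies in HER2-positive
breast cancer: AC-TH (doxorubicin/cyclophosphamide followed by paclitaxel
with trastuzumab) and TCH (docetaxel/carboplatin/trastuzumab).  The health
states are **stable** disease (on chemotherapy), **remission**, **relapse**
and **death**.  Cycles are one year long, the horizon is five cycles, and
death is absorbing and reachable only from relapse.  Each cycle the cohort
distribution is propagated through the annual transition matrix; costs and
quality-adjusted life-years (QALYs) accrue per state, are half-cycle
corrected, and are discounted at 5% per year.

Structural assumptions worth stating plainly:

* transition probabilities are constant over the horizon (no tunnel states,
  no time dependence);
* remission cannot return to stable disease, and death occurs only through
  relapse — so no deaths are possible in the first cycle of an all-stable
  cohort;
* the cohort enters the model 100% in the stable state.  The starting
  distribution is not part of the published parameter set; starting on
  active treatment with disease present is the natural reading, and the
  field is configurable (`init`).

## Deriving transition probabilities from summary statistics

Each arm is summarised by four clinical statistics (months, except the
dimensionless relative risk):

| statistic | AC-TH | TCH |
|---|---|---|
| relative risk of response, RR | 0.837 | 0.704 |
| median overall survival, OS | 44.3 | 35 |
| median time to progression, TTP | 7.2 | 10.35 |
| median duration of response, DOR | 5.6 | 4 |

The annual probabilities derive as:

* stable → remission: $1 - e^{-\mathrm{RR}/3}$,
* remission → relapse: $1 - e^{-0.75 \ln 2 / \mathrm{DOR}}$,
* relapse → death: $1 - e^{-0.75 \ln 2 / (\mathrm{OS} - \mathrm{TTP})}$,
* stable → relapse: $4 \times$ (remission → relapse),
* stay probabilities as row complements.

Two conventions require care, and both are deliberate design choices:

**Complement convention.**  The exponential expression
$e^{-0.75\ln 2/m}$ is the annual probability of *remaining* in a state
whose median residence time is $m$ months; the transition probability is
its complement.  This is the only reading that reproduces the published
best-estimate cells (e.g. $e^{-0.75\ln2/5.6} = 0.911$ is the printed
remission → remission value, and its complement 0.089 the remission →
relapse value).

**Printed-precision chaining.**  Under `rounding = "printed"` each derived
probability is rounded to its published precision *before* being chained
into dependent cells (stable → relapse is four times the *rounded*
remission → relapse probability, and the stay probabilities are
complements of rounded values).  The TCH remission → relapse cell is
printed at two decimals (0.12), every other cell at three; this is why the
TCH arm carries `rp_digits = 2`.  `rounding = "full"` never rounds, in
which case row groups sum to 1 exactly and no published cell is exactly
reproduced.  The bundled configuration uses printed precision, treating
the published table as the authoritative parameter set.

The constants 0.75 and 3 are unexplained scaling constants inherited from
the source parameterisation.  No derivation is attempted; they are exposed
as configuration fields (`constants$exit_factor`,
`constants$response_divisor`) rather than hidden as magic numbers.  The
TCH DOR is listed as 4 months while the accompanying printed formula uses
4.2; the parameter listing is taken as authoritative (default 4,
configurable), and at the printed two-decimal precision both give 0.12.

Sensitivity ranges are $\pm 20\%$ of the best estimate, capped at 1 for
probabilities and utilities.

## Values: utilities and costs

The published utility set has five entries for four states.  The default
one-to-one mapping is: stable 0.74 ("no recurrence, chemotherapeutic
period"), remission 0.85, relapse 0.50, death 0.  The alternatives (0.94
"after chemotherapy"; 0.74 "local recurrence") can be selected through the
configuration — which utility applies in which cycle was never specified,
so the unambiguous assignment is the default.

Costs have two components: a one-off intervention (chemotherapy) cost
charged undiscounted at cycle 1 — 3112 US\$ (AC-TH) and 1352 US\$ (TCH) —
and per-state per-cycle health-system costs.  Only per-strategy totals are
published (56,425 and 45,043 US\$), not the per-state breakdown, so the
bundled `state_costs` are **reconstructed**: relative weights
stable : remission : relapse = 1 : 0.35 : 2.2 were fixed a priori (active
disease under treatment costs more than remission follow-up; relapse
management is the most expensive), and one scale factor per arm was solved
so that the discounted half-cycle-corrected totals reproduce the published
health-system totals to within a dollar.  The weights are a modelling
choice, not data; any positive triple rescaled the same way reproduces the
totals, and users with real unit costs should replace them.  The bundled
fixture is named `acth_tch_synthetic.yaml` to make its reconstructed
status explicit.

## Accumulation conventions

* **Half-cycle correction** is trapezoidal: the membership credited to
  cycle $t$ is $(x_{t-1} + x_t)/2$.  Corrected totals therefore always lie
  between start-of-cycle and end-of-cycle counting.
* **Discounting** uses $1/(1+r)^{t-1}$: the first cycle is undiscounted.
  This matches charging the up-front chemotherapy cost at face value; the
  published description does not fix the convention either way.
* The one-off intervention cost is never half-cycle corrected or
  discounted.

## Incremental analysis

`incremental()` reports $\Delta C$, $\Delta E$, the ICER
$\Delta C/\Delta E$ and a dominance class (a strategy dominates when it is
both cheaper and more effective).  When dominance occurs the ICER is
negative and uninterpretable as a price, so the net monetary benefit
$\mathrm{NMB} = \lambda E - C$ is the primary decision output, at a
default threshold of $\lambda$ = 34,240 US\$/QALY (2015 Chinese GDP per
capita); 20,000 US\$/QALY is the default axis threshold for acceptability
curves.

A consequence the user should know: with the published transition
matrices, the AC-TH arm accumulates *more* QALYs than TCH (about 2.94 vs
2.77 discounted) and the base-case ICER is positive (about 76,000
US\$/QALY) — the published strategy-level QALY totals (3.4 vs 3.65) and
five-year state distributions are not reproducible from the published
matrices under any convention tried (initial distributions, rounding
modes, discounting and half-cycle settings).  The package therefore treats
those published totals as documentation, not as oracles: the test suite
verifies the engine against hand-computed traces, structural invariants
and a patient-level microsimulation instead, and the incremental
arithmetic is verified on the published totals taken as direct inputs.

## Sensitivity analysis

**One-way / tornado.**  Every parameter (14 transition cells, 3 utilities,
8 cost parameters) is varied to its range bounds with everything else at
best estimates, and parameters are ranked by the swing of the incremental
NMB at 20,000 US\$/QALY (the output metric is configurable to the ICER,
but NMB is the default for the same dominance reason as above).  Varying a
stay probability adjusts its complement (remission → relapse falls as
remission → remission rises); varying the stable → stable probability
rescales the two stable-row exits proportionally.  Ties in swing are
broken alphabetically so the ordering is deterministic, and the table can
be truncated to the parameters covering a cumulative share of total swing.

**Probabilistic (PSA).**  Each free parameter gets a distribution by
method of moments, treating its (lo, hi) range as a central 95% interval
($\mathrm{sd} = (hi - lo)/3.92$): beta for probabilities and utilities,
gamma for costs, a point mass when the range is degenerate.  Only the free
row parameters (stable → remission, stable → relapse, remission → relapse,
relapse → death) are sampled; stay probabilities are recomputed as
complements, because sampling a probability and its complement
independently would double-count the row's uncertainty.  If a sampled
stable row exceeds total probability 1, its two exits are rescaled
proportionally and the event is counted and reported.  The outer loop
(default 1000 draws) evaluates the *deterministic* cohort model — the
expected value given the parameters — rather than nesting a
microsimulation; the patient-level simulator exists separately as a
validation oracle.  Uncertainty intervals use the 2.5th and 97.5th
percentile ranks.  A single seed argument governs all draws.

**CEAC and CE plane.**  At each willingness-to-pay value the acceptability
of a strategy is the fraction of draws in which it has the highest NMB
(ties broken toward the cheaper strategy); fractions sum to 1 by
construction.  The cost-effectiveness plane labels draws by quadrant and
by position relative to the WTP ray, with points on the ray counted as
cost-effective.

## The synthetic-data generator and what a green test establishes

`generate_cohort()` draws patient records whose *arm-level statistical
structure* matches the published cohort summaries: response categories
from the arm multinomials (AC-TH, n = 25: PR 0.60, SD 0.12, PD 0.28;
TCH, n = 16: CR/SD/PD 0.0625 each, PR 0.8125), per-event adverse-event
grade buckets from the published G1–2/G3–4 incidence table, and optional
annual state paths sampled from a transition matrix.  Response categories
are metadata only — they do not feed the Markov matrix, because no link
between response class and transition probabilities was ever specified.

The generator emulates marginal frequencies, not patients: it has no
within-patient correlation between response and toxicity, no time-varying
adverse-event risk, and survival paths come from the model itself rather
than from observed curves.  A green test against synthetic data therefore
establishes that the *pipeline computes its stated quantities correctly*,
not that the model is clinically valid.

`microsimulate()` samples individual state paths (default 10,000
individuals) and is the convergence oracle for the cohort engine: counts
divided by n must agree with the deterministic trace within binomial
error.  `validate_cohort_model()` formalises this as a chi-squared
goodness-of-fit test.  Two cell constructions are offered: the default
partitions the cohort by year of death plus survivors — disjoint
multinomial cells, so the statistic is exactly chi-squared with
(cells − 1) degrees of freedom, which equals years − 1 here because the
first year has structurally zero deaths; the alternative `"cumulative"`
method compares cumulative per-year alive/dead tables, whose serial
correlation inflates the statistic above its nominal reference (measured
rejection roughly 0.09–0.15 at the 0.05 level instead of 0.05), and is
retained only for comparability.

## Numerical choices

* Row-stochasticity is enforced to 1e−12 at matrix construction and 1e−10
  during iteration; these bounds are asserted, not silently repaired.
* Printed-precision rounding is half-up via `round()` to 3 decimals
  (2 for the TCH remission → relapse cell); range cells round to 4.
* An infeasible derivation (stable-row exits summing past 1, e.g. a very
  short DOR) is an error at derivation time, not a silent clamp; only
  *sampled* rows in the PSA are rescaled, and loudly.
* Beta fits reject ranges whose implied variance is unattainable
  (`var >= mean(1-mean)`); degenerate ranges fall back to point masses.
* Quantile type 1 (pure order statistics) is used for PSA intervals, so a
  1000-draw interval is literally the 25th and 975th ordered draws.

## Known limitations

Constant transition probabilities over five years; no adverse-event costs
attached to individual toxicity grades (prophylaxis costs sit inside the
aggregate intervention cost); no expected-value-of-perfect-information
analysis; no correlated parameter sampling; two-strategy comparison only,
so extended dominance never arises.  The reconstructed state costs
reproduce published totals but not any real price list, and the published
QALY totals are unreachable from the published matrices, as discussed
above.
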