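---
title: "Modelling the cost-effectiveness of ART treatment strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of ART treatment strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artcea)
```

## The decision problem

Women of advanced maternal age (35 years and over) face sharply declining
success rates with standard in-vitro fertilisation, and several more
expensive alternatives compete for the same decision: screening embryos for
aneuploidy (PGT-A), using oocytes donated by a younger woman, or returning to
oocytes the woman herself banked at a younger age ("social freezing").
`artcea` implements a cohort decision model that compares these four
strategies on two outcomes — the cumulative live-birth rate (CLBR, the
probability of at least one live birth over the whole treatment pathway) and
the expected treatment cost — and combines them into incremental
cost-effectiveness ratios (ICERs):

$$\mathrm{ICER} = \frac{E[C_{\text{alt}}] - E[C_{\text{std}}]}
                       {\mathrm{CLBR}_{\text{alt}} - \mathrm{CLBR}_{\text{std}}}$$

the extra cost per additional live birth of adopting an alternative over
standard autologous treatment. An alternative that is both more effective and
cheaper is reported as *dominant* ("more effective and cost saving") rather
than as a ratio.

## Model structure

Each strategy is an ordered, finite sequence of *attempt stages*, where one
stage is one complete treatment cycle: an ovarian-stimulation episode
together with its bundled embryo transfers. This granularity is dictated by
the input data — published live-birth rates for these treatments are
cumulative per stimulation episode (per oocyte pick-up, OPU), not per
individual transfer — so individual frozen-transfer sub-cycles are not
simulated; their costs are bundled into the stage's cost items.

Within a stage, an entering woman:

1. reaches OPU with the age-band probability $q$, otherwise the cycle is
   *cancelled* (poor response or hyperstimulation);
2. on a cancelled cycle, either re-attempts the stage once (with the age-band
   progression probability $c$) or ends treatment; a second cancellation ends
   treatment — the single re-attempt keeps the outcome tree finite and
   matches the clinical reading that a cancelled first cycle may be followed
   by one further fresh cycle;
3. on reaching OPU, achieves a live birth with the stage's rate $p$
   (absorbing), or fails and either continues to the next stage (probability
   $c$ again) or ends.

Live birth and end are absorbing. Per entering unit of cohort mass the stage
therefore generates $o = q\,(1 + (1-q)\,c)$ expected OPU events,
$x = (1-q)(1 + c\,(1-q))$ expected cancellations, $o\,p$ live births, and
$o\,(1-p)\,c$ continuing mass. The same progression probability is used after
both a failed complete cycle and a cancelled cycle (the data source reports a
single "progression to fresh cycle" figure); the two hooks are kept separate
in the stage definition so sensitivity analyses can split them. All
strategies complete within a year, so nothing is discounted and age is fixed
over a pathway.

Two independent implementations of this process ship in the package and are
tested against each other: a forward cohort recursion (`run_cohort()`,
closed-form per stage) and an exhaustive enumeration of every pathway through
the tree (`enumerate_pathways()`), which agree on CLBR and expected cost to
below $10^{-10}$ on every built-in and randomly generated strategy. A third,
fully analytic recursion for homogeneous toy strategies
(`closed_form_toy()`) pins both down on a $5^3 \times 4$ parameter grid.

## The four strategies

* **Standard autologous** — two complete autologous cycles (fresh transfer
  plus two bundled frozen transfers per episode).
* **PGT-A** — two complete autologous cycles with aneuploidy screening
  (fresh plus one bundled frozen transfer); the second cycle's live-birth
  rate is reduced by 10% (`pgta_subsequent_cycle_multiplier = 0.90`),
  reflecting the poorer prognosis of a repeat screened cycle.
* **Donor** — two complete autologous cycles followed by up to two
  donor-oocyte transfer cycles. The recipient undergoes transfer only, so
  donor stages have no cancellation branch. The donor live-birth schedule is
  treated as a per-cycle rate: its sources report outcomes per donor cycle,
  and a per-cycle reading is also the one consistent with the published
  incremental results, since in this model the donor ICER reduces to the
  donor cycle cost divided by the per-cycle live-birth rate.
* **Social freezing** — oocytes banked at age 32 (`freeze_age`), with the
  woman returning at 40-45 for two thaw transfer cycles. Banking is modelled
  as a deterministic upfront cost (two OPU procedures are assumed to retrieve
  sufficient oocytes, so banking success is certain): the banking bundle, the
  thaw-cycles bundle, and storage per year times the years between freezing
  and return. The published success schedule for this strategy is cumulative
  over both thaw cycles, so a per-cycle rate is backed out by solving
  $1-(1-p)^2 = \mathrm{CLBR}$; the same back-out rule would apply to any
  schedule that is cumulative over its stage count. Applying the progression
  probability between the two thaw cycles means the realised strategy CLBR
  sits somewhat below the table figure, which assumes both cycles are used.
  A `return_rate` setting (default 1: all women return) scales the entering
  mass; banking costs accrue regardless of return.

## Costs, perspectives, currency

Each procedure bundle carries two components: the public-insurance rebate
and the patient's out-of-pocket share. The *societal* perspective sums both;
the *patient* perspective counts out-of-pocket only, so patient cost can
never exceed societal cost. Accrual rules: the complete-cycle item accrues
once per stage reaching OPU, the cancelled-cycle item once per cancellation,
the PGT-A item per screened stage reaching OPU, the donor item per donor
stage, and the social-freezing items upfront. All amounts are 2019 values in
the analysis currency of the built-in cost table; conversion (division by
the purchasing-power-parity rate, 1.41 per US dollar) is applied only for
display, and rounding only at report time.

## Parameters that matter

| Setting | Default | Meaning |
|---|---|---|
| `ppp_aud_per_usd` | 1.41 | PPP rate for USD display |
| `wtp_threshold` | 50,000 | willingness-to-pay per additional live birth |
| `psa_replicates` | 10,000 | Monte Carlo replicates |
| `probability_cv`, `cost_cv` | 0.10 | uncertainty scale for PSA draws |
| `pgta_subsequent_cycle_multiplier` | 0.90 | second screened cycle penalty |
| `freeze_age` | 32 | age at oocyte banking |
| `return_rate` | 1.0 | share of banking women who return |

The probability and cost coefficients of variation deserve a note: the
published point estimates come without standard errors, so a common CV of
0.10 — a typical magnitude for registry-based rates — is an explicit,
user-configurable stand-in, not an estimate.

Published rate schedules are per single year of age here; when a user
supplies rates by 5-year band instead, `interpolate_age_rates()` converts
them to a per-age schedule by least-squares logistic regression on the logit
scale (linear in age in log-odds), the standard provenance mechanism for
these tables. Interpolation is not used at runtime for the built-in inputs,
which are already age-specific.

## Probabilistic sensitivity analysis

Every probability receives a beta distribution and every nonzero cost
component a gamma distribution, moment-matched to the point estimate $m$ and
variance $(\mathrm{cv}\,m)^2$: beta shapes $\alpha = m\nu$, $\beta=(1-m)\nu$
with $\nu = m(1-m)/v - 1$ (infeasible when $v \ge m(1-m)$, which raises an
error), gamma shape $1/\mathrm{cv}^2$ and scale $m\,\mathrm{cv}^2$. Draws
are independent across parameters — no correlation structure is asserted —
and shared across strategies within a replicate (common random numbers), so
incremental pairs are coherent. A fixed seed makes the entire analysis,
including every report file, bit-reproducible.

Percentile intervals (2.5th/97.5th) use linear interpolation between order
statistics (`stats::quantile` type 7). Because replicate ICERs can straddle
quadrants, two summary conventions are computed and labelled: the ratio of
mean increments (`icer_of_means`) and the mean of replicate ratios
(`mean_ratio`); interval bounds are offered both on the raw replicate ratio
(default, which can legitimately span negative to positive) and restricted
to ratio-classified draws with the dominant/dominated shares alongside.
Cost-effectiveness acceptability uses the net-monetary-benefit rule: the
fraction of replicates with $\lambda\,\Delta E - \Delta C > 0$ at
willingness-to-pay $\lambda$.

One property of PSA means is worth stating explicitly: the model is
nonlinear in its parameters (the OPU probability enters quadratically
through the re-attempt term, and stage-2 entry mass squares the shared
continuation draw), so the mean of replicate outcomes estimates
$E[f(\theta)]$, which differs from the deterministic $f(E[\theta])$ by a
Jensen gap of order $\mathrm{cv}^2$ — roughly 1-2% of the increments at the
default CV. At large replicate counts this gap is many Monte Carlo standard
errors wide; it is a real feature of probabilistic analysis of nonlinear
models, not sampling noise, and the package makes no attempt to hide it.

## Synthetic scenarios

`generate_inputs()` produces random but structurally valid parameter sets:
age schedules that decline logistically (a constant per-year multiplicative
decline in the odds of success, mirroring the interpolation model), age-band
procedure probabilities, and positive two-payer costs preserving the
built-in zero-rebate pattern. It emulates the *parameter-level* structure of
real inputs only — it does not emulate record-level registry data,
between-parameter correlation, or secular trends — so tests passing on
synthetic scenarios demonstrate engine correctness, not clinical realism.
`generate_toy_strategy()` draws small arbitrary strategies for
property-based testing of the engine against the enumeration oracle.

## Numerical choices and degenerate inputs

* Oracle equivalences are asserted to $10^{-10}$-$10^{-12}$; probability
  conservation at every stage to $10^{-12}$.
* Boundary probabilities (0 or 1) are legal everywhere and handled exactly;
  beta sampling leaves degenerate parameters (mass at 0 or 1) fixed, and
  zero-mean cost components stay zero.
* A strategy whose live-birth rates are all zero has CLBR 0; a first-stage
  certain success absorbs the whole cohort and later stages carry zero mass.
* `per_cycle_rate()` requires a cumulative rate strictly below 1.
* Zero CLBR yields an undefined cost per live birth (`NA`), and a zero
  effect difference yields an "undefined" ICER classification rather than an
  infinite ratio.

## Problem sizes used in the test suite

The shipped tests run the full model grid (4 strategies, ages 35-45),
200 randomly generated strategies against the enumeration oracle, the
complete $5^3 \times 4$ closed-form grid, and a 10,000-replicate PSA with
fixed seed; smaller replicate counts (50-2,000) are used where a property
does not require the full run. These sizes were chosen to exercise every
code path at the model's published scale while keeping a single-CPU test run
comfortably short.

## Known limitations

* The model is a cohort (expected-value) model: no individual-level
  microsimulation, no embryo-level modelling, no multiple-birth or perinatal
  outcomes, and no quality-adjusted outcome measure — effectiveness is the
  live birth itself.
* Treatment beyond the defined pathways (third autologous cycles, mixed
  strategies) is out of scope, as are insurance rules beyond the fixed
  two-payer split and any inflation adjustment beyond the fixed 2019 values.
* Costs are not discounted across the banking-to-return gap for social
  freezing (up to 13 years); with a positive discount rate the upfront
  banking cost would weigh more heavily. The gap is flagged as a sensitivity
  knob rather than modelled.
* The default 100% return rate after banking is optimistic — reported return
  rates are far lower — and directly scales the social-freezing CLBR.
* PSA uncertainty magnitudes are stand-ins (CV 0.10), since the sources
  publish no standard errors.
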