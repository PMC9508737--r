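# artcea

Cost-effectiveness modelling of assisted reproductive technology (ART)
treatment strategies for women of advanced maternal age (35–45 years).

Fertility treatment success falls steeply with age, and women and clinicians
choose between a standard course of autologous IVF and more expensive
alternatives: embryo aneuploidy screening (PGT-A), donor oocytes, or
returning to oocytes banked at a younger age ("social freezing"). `artcea`
implements a Markov-style cohort decision model of these four strategies for
health economists and HTA analysts. Each strategy is a finite sequence of
complete treatment cycles with absorbing live-birth/end states; per entering
cohort unit a stage with OPU probability $q$, live-birth rate $p$ and
progression probability $c$ yields $o = q(1+(1-q)c)$ expected oocyte
pick-ups, $o\,p$ live births, and $o(1-p)c$ mass continuing to the next
cycle. The package computes, per strategy and start age:

* the cumulative live-birth rate $\mathrm{CLBR} = \sum_s m_s\, o_s\, p_s$
  over the pathway,
* expected cost under a societal (rebate + out-of-pocket) and a patient
  (out-of-pocket only) perspective,
* incremental cost-effectiveness ratios versus standard care,
  $\mathrm{ICER} = \Delta E[C] / \Delta \mathrm{CLBR}$, with dominance
  classification ("more effective and cost saving"),
* a probabilistic sensitivity analysis: 10,000 Monte Carlo replicates with
  moment-matched beta (probabilities) and gamma (costs) distributions,
  percentile intervals, cost-effectiveness plane points, and acceptability
  curves under the net-monetary-benefit rule.

The published model inputs (age-specific live-birth rates per complete
cycle, age-band OPU/progression probabilities, and 2019 two-payer procedure
costs) ship as a built-in fixture; user scenarios load from YAML. An
exhaustive pathway-enumeration oracle and a synthetic-scenario generator
back the test suite. See `vignettes/art-cost-effectiveness.Rmd` for the full
model description.

## Worked example

```r
library(artcea)
fx <- builtin_fixture()

strategy_outcome("standard", 40, fx)
#> standard @ age 40: CLBR 0.2424, cost 17002 (societal) / 6874 (patient)
```

A 40-year-old starting standard autologous ART has a 24.2% chance of a live
birth over two complete cycles, at an expected societal cost of 17,002
(2019 dollars), of which 6,874 is paid out of pocket.

```r
icer(strategy_outcome("standard", 40, fx),
     strategy_outcome("social_freezing", 40, fx))
#> social_freezing vs standard @ age 40 (societal): dC=-2317 dE=+0.0627
#>   -> more effective and cost saving

icer(strategy_outcome("standard", 40, fx),
     strategy_outcome("donor", 40, fx))
#> donor vs standard @ age 40 (societal): dC=5692 dE=+0.1540
#>   -> ICER 36972 per additional live birth
```

At 40, having banked oocytes at 32 dominates standard care (6.3 percentage
points more live births for 2,317 less), while donor ART buys 15.4 extra
percentage points at 36,972 per additional live birth. Parameter uncertainty:

```r
psa <- run_psa(fx, ages = 40, n_replicates = 10000, seed = 42)
prob_cost_effective(psa, 50000)
#>   age     alternative   wtp probability
#> 1  40            pgta 50000      0.0144
#> 2  40 social_freezing 50000      0.9802
#> 3  40           donor 50000      0.9818
```

At a willingness-to-pay of 50,000 per additional live birth, social freezing
and donor ART are cost-effective in ~98% of replicates at age 40.

CSV reports (deterministic outcome/ICER tables, PSA summaries, CE-plane and
CEAC tables) are written by `cmd_deterministic()` / `cmd_psa()`, or from a
shell via the thin wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "artcea.R", package = "artcea"))')" \
  deterministic --ages 35-45 --perspective societal --outdir out/
```

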