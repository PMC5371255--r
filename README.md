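# taskshiftCBA

Societal-perspective cost-benefit analysis of task-shifting group
cognitive-behavioral therapy (CBT) for alcohol reduction to trained
paraprofessionals, rolled out to 13,440 HIV-positive outpatients across 12
Kenyan sites over five years. The package is for health economists and
implementation researchers who want to reproduce, stress-test, or
reconfigure the model: every input — cost ledgers, trial effect sizes,
wages, CPI, exchange rate, rollout schedule — is a plain-text fixture or a
function argument.

## The model

Costs are ingredient-based (units × unit cost in KES, converted at 84.53
KES/USD): a one-off training budget plus an annual per-site budget for each
of 12 sites over 5 years. Benefits accrue per participant for an
`effect_length` of years (base case 2) from enrollment:

* **Benefit 1, averted HIV treatment costs:**
  `B1 = Δ × AF × C`, with Δ = 0.31 the CBT-vs-usual-care difference in
  90-day abstinence, AF = 0.13 the alcohol-attributable fraction of HIV
  incidence, and C ≈ $269 the annual per-patient treatment cost
  (CPI-inflated 2009 non-drug components + 2013 ARV regimen).
* **Benefit 2, adherence-mediated productivity:**
  `B2 = Δ × G × (w_LFP + f × w_HP)`, with G = 19/69 − 112/1439 ≈ 0.1975
  the adherence gain from abstinence, `w_LFP = 0.19 × 76.93 × 12` the
  annualized labor-force wage gain (both sexes), and
  `w_HP = (1.056 + 1.945) × 0.85 × 48` the annualized household-production
  value, counted for the female fraction f = ½.

All flows are constant 2013 USD, discounted at 3%/year end-of-year (year 1
undiscounted); the benefit-to-cost ratio (BCR) is discounted benefits over
discounted costs. One-way (tornado) sensitivity, Monte Carlo probabilistic
sensitivity analysis (10,000 replications per effect-length scenario), and
a person-level microsimulation oracle sit on top of the deterministic
engine. See `vignettes/cost-benefit-model.Rmd` for the full account.

## Worked example

```r
library(taskshiftCBA)

res <- run_cba()   # bundled base-case fixtures
res
#> Cost-benefit analysis (constant 2013 USD, end-of-year discounting)
#>   effect length:              2 year(s); horizon 6 years
#>   total discounted costs:     $556,000
#>   total discounted benefits:  $631,000
#>   benefit-to-cost ratio:      1.13
#>   net benefit:                $75,000
#>   cost per participant:       $44 (undiscounted)

per_person_year_benefit(model_parameters(), economic_context())
#> Per-person-year benefits (2013 USD)
#>   averted HIV treatment (benefit 1):  10.85
#>   labor-force productivity:           10.74
#>   household productivity (females):    3.75
#>   total:                              25.34
```

Each treated person generates about $25.34/year in monetized benefits
($10.85 from averted HIV treatment costs, $14.49 from productivity) for
two years, against a $44 program cost — so the rollout returns $1.13 per
dollar spent. The return hinges on how long the treatment effect lasts:

```r
sapply(c(1, 5, 10), function(L) round(run_cba(effect_length = L)$bcr, 2))
#> [1] 0.58 2.72 5.06
```

A one-year effect is not cost-neutral; five- and ten-year effects are
strongly cost-saving. `tornado(model_inputs())` ranks all inputs by their
BCR spread, and `run_psa(psa_config(seed = 1))` runs the probabilistic
analysis. A thin command-line wrapper with `run`, `tornado`, `psa`, and
`simulate` subcommands is installed at
`system.file("scripts", "cba_cli.R", package = "taskshiftCBA")`.

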