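---
title: "A cost-benefit model of task-shifted CBT for alcohol reduction among HIV+ outpatients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cost-benefit model of task-shifted CBT for alcohol reduction among HIV+ outpatients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskshiftCBA)
```

## The decision problem

Kenya has a generalized HIV epidemic, high rates of hazardous alcohol use,
and an acute shortage of mental-health professionals. One scalable response
is *task-shifting*: training paraprofessional counselors to deliver a
structured group cognitive-behavioral therapy (CBT) that reduces alcohol
use among HIV-positive outpatients. `taskshiftCBA` models the economics of
rolling that program out to 13,440 outpatients at 12 sites over five years,
from a societal perspective, and asks whether the monetized benefits exceed
the program's costs.

The model is a deterministic discounted cash-flow cohort model with two
layers of uncertainty analysis on top (one-way and probabilistic), plus an
individual-level microsimulation used as an internal consistency oracle.

## Costs

Costs are ingredient-based: every line is `units x unit cost` in Kenyan
shillings, converted at a fixed 84.53 KES/USD. Two ledgers are bundled as
CSV fixtures:

* **Training** (one-off, year 1): counselor and psychiatry consultants,
  per diems, materials, conference facilities, and start-up furniture and
  equipment — KES 4,369,168 ($51,688).
* **Per-site annual budget** (each of 12 sites, each of 5 years): a
  full-time counselor pair, a quarter-time diploma nurse, supplies, and
  participant transport payments — KES 752,555 ($8,903).

```{r costs}
res <- run_cba()
round(res$per_year_costs$amounts)
```

Year 1 therefore costs about $158,500 and years 2–5 about $106,800 each.
Each site serves 160 participants in its first year and 240 in years 2–5
(two counselors move from two to three groups per week), giving the 13,440
total. An alternative 320-per-site schedule can be configured; only the
160/240 plan is consistent with the 13,440 denominator, so it is the
default. Dividing undiscounted total costs by 13,440 gives a unit cost of
about $44 per participant ($41 discounted).

All flows are assumed to occur at the end of each year and are discounted
at 3%/year, so year 1 is undiscounted and year *t* is divided by
1.03^(t−1). Costs denominated in 2009 USD are restated in 2013 USD with
the Kenyan CPI (140.103 on a 2009 = 100 base).

## Benefits

Each participant accrues two annual benefits for `effect_length` years
(base case: 2) starting in their enrollment year.

**Benefit 1 — averted HIV treatment costs.** The product of

* the abstinence effect Δ = 0.69 − 0.38 = 0.31 (90-day abstinence, CBT
  minus usual care),
* the fraction of new HIV infections attributable to alcohol use (0.13),
* the annual per-patient cost of treating HIV: the CPI-inflated 2009
  non-drug components (lab tests 32, visits 24, support services 0.4,
  fixed costs 32 → $124 in 2013 USD) plus the 2013 first-line ARV regimen
  ($145.47), about $269/patient-year.

That gives 0.31 × 0.13 × 269.3 ≈ **$10.85** per person-year.

**Benefit 2 — productivity gains via ARV adherence.** Abstinence raises
the probability of full ARV adherence by 19/69 − 112/1439 ≈ 0.1975
(non-adherence among hazardous drinkers minus among non-drinkers), and
adherence raises productivity:

* *Labor-force participation (LFP)*, both sexes: a 19% rise in weekly
  hours worked (+4.6 h on a 24.3 h baseline, SE 1.88), valued as a
  proportional rise in annual minimum-wage income, 0.19 × $76.93 × 12.
* *Household productivity (HP)*, females only (half the cohort): 1.056 +
  1.945 extra weekly hours (firewood, water), valued at the $0.85/h
  house-worker wage over 48 weeks/year.

So benefit 2 = 0.31 × 0.1975 × (175.40 + 0.5 × 122.44) ≈ **$14.49** per
person-year.

```{r benefits}
per_person_year_benefit(model_parameters(), economic_context())
```

### The annualization convention

The sources give the LFP gain as weekly hours and a monthly wage, but no
explicit hours-to-money rule. We fix the convention by requiring internal
consistency with the model's own aggregate outputs: among the candidate
conventions ({proportional rise in annual wage income vs. hourly valuation
of the gained hours} × {48 vs. 52 working weeks for HP}), only the
proportional-wage LFP rule combined with 48-week HP annualization
reproduces both the per-person benefit 2 value ($14.50) and the aggregate
benefit total (≈$628k) simultaneously. Both constants
(`annualization_weeks`, `months_per_year`) are ordinary parameters and can
be changed; the defaults encode this reconstruction and are flagged as
such here.

### Headline results

```{r headline}
res
```

The benefit-to-cost ratio (BCR) is total discounted benefits over total
discounted costs; values above 1 mean the program is cost-saving from the
societal perspective. The time horizon is never configured independently:
it is `n_cost_years + effect_length - 1` (6 years in the base case), so
the final cohort's benefits are always counted in full.

## One-way sensitivity (tornado)

`tornado()` re-runs the full deterministic model with one input at a time
at each bound of its range, everything else at base, and ranks inputs by
the induced BCR spread. Ranges for the Table-of-inputs parameters come
from the bundled configuration (95% CIs where available, otherwise the
observed or assumed range). The composites Δ (0.21–0.41) and the adherence
gain (0.1475–0.2475) are overridden directly rather than re-derived from
their components, because their ranges are stated on the composites.

Three structural inputs have no published bounds; the defaults are set
once here and are configurable: discount rate 0–6% (brackets the 3% base
with the common 0% and 6% reference cases), participant transport 0–500
KES/visit (no reimbursement up to 2.5× base), and a 0.5–2× multiplier on
all program costs. Treatment-effect length is varied over 1–10 years.

```{r tornado}
tor <- tornado(model_inputs())
head(tor, 4)
```

Effect length dominates, as the deterministic scenario analysis already
suggests: the BCR is 0.58, 2.72, and 5.05–5.06 at effect lengths of 1, 5,
and 10 years.

## Probabilistic sensitivity analysis

`run_psa()` draws all uncertain inputs simultaneously, 10,000 replications
per effect-length scenario (1, 2, 3, 4, 5, 10 years), and evaluates the
deterministic model per draw. Distribution assignment follows the model's
stated rules:

* **Costs** (the four non-drug components and the ARV regimen):
  right-skewed lognormal with median at the base value and sigma =
  log(high/low)/3.92, so the central 95% of mass spans the sensitivity
  range. The original parameterization is not recoverable from the
  published description; this is the standard PSA choice for cost inputs
  and is configurable per input.
* **Inputs with reported CIs** (LFP hours, the two HP hour gains): normal
  with the reported SE. The LFP CI is reported on the hours scale (mean
  4.6, SE 1.88, baseline 24.3 h); we carry it to the fraction scale as
  N(0.19, 1.88/24.3), anchoring the mean at the printed 19% base so the
  stochastic analyses are centred on the deterministic model.
* **Everything else** (Δ, the attributable fraction, the adherence gain,
  both wages): uniform over the stated range.

Fraction-scale draws are clamped to [0, 1] and monetary/hour draws to
>= 0; clamp counts are attached to the result. Program rollout costs are
ledger quantities, not uncertain inputs in the configuration table, and
are held at base. A failed replicate aborts the run rather than being
dropped silently.

```{r psa}
psa <- run_psa(psa_config(n_reps = 2000, seed = 1))
round(as.data.frame(psa)[, 1:5], 3)
```

Mean BCRs rise strictly with effect length. Two interval constructions
are reported, because the published description does not say which was
used: the 2.5–97.5 percentile interval of replicate BCRs (`ci_low`,
`ci_high`) and a normal CI of the mean (`ci_mean_low`, `ci_mean_high`).

**A known, deliberate discrepancy.** Under these sampling rules the PSA
means sit *below* the deterministic BCR (2-year mean ≈ 1.0 vs. 1.13),
mostly because the alcohol-attributable fraction is drawn uniformly over
1.8–16.5%, whose mean (9.15%) is well below the 13% base. The published
account of this model reports PSA means *above* the deterministic value
(e.g. 1.28 at 2 years), which no parameterization consistent with its
stated distribution rules appears able to produce; the exact cost
parameterization behind those figures is not recoverable. We implement the
stated rules faithfully and document the gap rather than re-tuning
distributions to match the printed means; the corresponding acceptance
check is expected to fail and says so.

## The microsimulation oracle

`generate_cohort()` simulates individual participants under the model's
assumed data-generating process: sex ~ Bernoulli(0.5); CBT-attributable
sustained abstinence ~ Bernoulli(0.31); adherence gain ~ Bernoulli(0.1975)
among the abstinent; LFP gain ~ N(0.19, 1.88/24.3) on the fraction scale;
HP hour gains (females only) from the two normal components. Negative
hour draws are clamped at 0 (counted on the roster); at the base SEs this
raises means by well under 0.1% and the closed form, which uses means, is
unaffected. `microsim_benefit_total()` accrues and discounts each
person's realized benefits with the engine's exact conventions.

The person-level total is an unbiased estimator of the closed-form
discounted benefit total; the test suite checks agreement within 3 Monte
Carlo standard errors over 200 independent rosters of 13,440 participants,
plus linearity in cohort size and exact seed reproducibility. Passing
these checks validates the *arithmetic consistency* of the cohort closed
forms with their person-level interpretation — it says nothing about how
real Kenyan outpatients would respond, since the generator shares all of
the model's structural assumptions (independent Bernoulli responses, a
two-year rectangular effect profile, no secondary transmission dynamics,
no correlation between adherence and productivity draws).

## Numerical choices and problem sizes

* Internal arithmetic is never rounded; rounding (BCR to 2 dp, totals to
  the nearest $1,000, per-person values to the cent) happens only in
  printing and reports, which carry raw-precision columns alongside.
* Ledger line totals supplied in input files are checked against
  `units x unit cost` to within 1 KES (the printed tables round).
* Tornado ordering is deterministic: decreasing spread, ties broken
  alphabetically.
* All randomness flows through `set.seed()` on user-supplied integer
  seeds; PSA results and rosters are bit-identical under the same seed.
* The bundled test suite runs the PSA at 10,000 replications x 6
  scenarios (vectorized, a few seconds) and the microsim oracle at 200
  rosters x 13,440 participants; both match the scales the model is
  defined at, so no scaled-down surrogate is needed.

## Limitations

* The treatment effect is a sustained-abstinence probability applied
  identically in each benefit year; no decay within the effect window.
* HIV benefit uses an attributable-fraction shortcut, not transmission
  dynamics; benefits of averted *secondary* infections are excluded.
* The exchange rate is a single constant for all years, and per-site
  budgets are flat across years 2–5 (constant-2013-USD framing; no wage
  inflation).
* The per-site ledger's participant-payment line reflects 160
  participants (960 visits) even in 240-participant years, as the source
  budget prints it; a config flag (`scale_ledger()` on the
  `"Participant Payments"` category) can scale it with enrollment.
* The published PSA means are not reproducible from the stated
  distribution rules (see above); PSA output should be read as this
  package's parameterization, not as a replication of those figures.
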