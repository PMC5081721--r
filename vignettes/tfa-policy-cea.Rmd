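---
title: "Modelling EU trans-fat policy options: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling EU trans-fat policy options: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfacea)
library(dplyr)
```

## The decision problem

Industrially produced trans fatty acids (iTFAs) raise the risk of
coronary artery disease (CAD). `tfacea` compares four EU-level policy
responses on lifetime costs and health:

1. **reference** — no EU-level action; national efforts and industry
   innovation still remove iTFAs from the food supply over 10 years;
2. **voluntary** — EU-level voluntary agreements; total removal after 5
   years, plus a food-inspection programme;
3. **labeling** — mandatory trans-fat labeling of prepackaged foods; the
   prepackaged half of intake (50%) disappears over 3 years after a 2-year
   implementation lag, the rest follows the reference path; information
   measures and food inspection are funded publicly;
4. **legal_limit** — a legislative limit on iTFA content; total removal in
   2 years, plus food inspection.

Each option is evaluated for a closed, sex- and age-stratified EU-like
cohort (508 million people) followed in yearly cycles over an 85-year
horizon, with 3.5% annual discounting of both costs and effects. Options
are compared by incremental costs, incremental disability-adjusted life
years (DALYs), incremental cost-effectiveness ratios (ICERs), dominance,
and WHO GDP-per-capita cost-effectiveness thresholds (1x and 3x €23,300
for the EU).

## The state-transition model

The health model is a four-state Markov cohort model: **Well**, **CAD**
(acute event year, at most one cycle), **History of CAD**, and **Death**
(absorbing). Eight transition probabilities govern the flows per (age,
sex, year):

* first CAD event from Well: the baseline annual event probability
  `p0(age, sex)` from the morbidity table, scaled by the intake relative
  risk (below);
* acute-event resolution: death with the case fatality `cf(age, sex)`,
  otherwise passage to History; repeat events carry a fatality of
  `min(1, 1.5 * cf)`;
* repeat CAD event from History: `min(1, 1.5 * p_first)`;
* non-CAD death from Well and History: the all-cause probability with the
  CAD-death hazard removed by hazard subtraction,
  `q_other = 1 - exp(-[-ln(1 - q_all) + ln(1 - p_first * cf)])`, guarded
  to `[0, 1]`.

The hazard subtraction avoids double counting CAD deaths inside all-cause
mortality; whether the source life tables already excluded CAD deaths is
not documented, so this correction is an explicit assumption of the
package. Every outgoing row sums to one by construction, the cohort is
exactly conserved (alive + dead = initial population each cycle), and the
top age of the grid is absorbing (`q = 1`), which bounds the horizon.
Occupants who age past the top of the grid are held at the top age and die
there within a cycle. Events are counted in the cycle they occur; acute
deaths occur in the following cycle, when the acute state resolves. No
half-cycle correction is applied; with yearly cycles and an 85-year
horizon its effect is small relative to the parameter uncertainty, but
totals are therefore slightly "start-of-cycle" weighted.

The engine is an expected-value (deterministic) cohort model:
stochasticity enters only through parameter draws in the probabilistic
sensitivity analysis. An individual-level microsimulation exists in the
test suite purely as an oracle: on a small instance (10,000 people at
three ages, 20 years, 50 seeded replicates) the cohort engine must match
its event and death counts within three Monte-Carlo standard errors.

## Intake trajectories and the dose-response

Initial population intake is 0.3 E% (percent of total energy) in the base
case, with alternative scenarios at 0.15 (`s1`), 0.45 (`s2`) and 0.7 E%
(`s3`). All options reach 0 E% eventually; only the speed differs. The
shape of the decline between the stated anchor points is not documented in
the source analysis, so it is configurable (`linear`, the default, or
`exponential`, rescaled to still reach exactly zero on schedule). Age- and
sex-specific initial intakes default to the scenario mean for every
stratum; multipliers can be supplied when external intake tables are
available.

The CAD relative risk is 1.23 (95% CI 1.11-1.37) per 2 E% of trans-fat
intake replacing carbohydrate. The baseline event probabilities already
embed today's intake, so the model scales them by
`RR^((E_t - E_0) / 2)` — log-linear dose scaling, the standard convention
for pooled relative risks, applied to the intake *change* since year 0.
With RR = 1 all four options produce identical transition tables, a
property the tests check.

## Costs and DALYs

All monetary values are 2011 euros. Three cost groups are modelled
(values per the published cost table):

* **acute-event bundle**, per CAD event: in-patient care (€3557.46),
  medication (€1605.36), accident and emergency (€213.78), outpatient
  care (€854.56);
* **chronic bundle**, per person-year lived in History: primary care
  (€617.34), informal care (€6440.19), production losses from morbidity
  (€2158.88);
* **mortality**: production losses per CAD death (€5101.94);
* **policy measures**, per alive person per year: food inspection (€0.86)
  for the whole horizon under voluntary, labeling and legal-limit;
  school-based interventions (€1.15), worksite interventions (€4.48),
  mass-media campaigns (€1.90) and physician counseling (€8.28) under
  labeling only, for the first 5 years (configurable; the source does not
  state this duration).

The split of disease costs into per-event versus per-prevalent-year
bundles is not documented in the source beyond the category list; the
assignment above is a package decision and every cost is configurable.

DALYs are years of life lost (YLL) plus years lived with disability
(YLD). YLL values each CAD death with the discounted remaining period
life expectancy at the age and sex of death, computed from the run's own
life table by backward recursion — no age-weighting, consistent with
GBD-2010 practice. YLD weights acute events (weight 0.422, one cycle) and
History person-years (weight 0.08); these weights ship in the packaged
example configuration (`inst/extdata/eu_default_config.yaml`) as
externally sourced GBD-2010 values rather than hard-coded defaults.

## The synthetic input generator

No deposited life tables, morbidity tables or population data accompany
the source analysis, so the package generates synthetic EU-like inputs
with the statistical structure the model assumes:

* **all-cause mortality**: Gompertz hazard `alpha * exp(beta * age)`
  (defaults `alpha = 5e-5`, `beta = 0.09`) converted to annual
  probabilities via `1 - exp(-hazard)`, male hazard 1.5x female. This
  yields adult mortality from ~0.2%/y at age 40 to ~30%/y at 100;
* **CAD events**: log-linear hazard in age (slope 0.08/y), male:female
  hazard ratio exactly 2, case fatality 0.02 + 0.002 per year of age;
* **population**: 508 million people, flat through midlife with a
  logistic decline centred at age 78, even sex split, small seeded jitter
  below age 61 (so counts stay monotone at older ages). Rate curves are
  deterministic in the parameters; only the pyramid uses the seed.

The event-rate scale (`cad_rate_scale = 1.2e-4`) is calibrated so the
reference arm's discounted 85-year cost burden matches the ~€1.1e13 order
reported for the EU baseline. The implied crude event rate (~2% per
person-year) is far above true CAD incidence: the source derived event
probabilities from *all* ischaemic-heart-disease hospital discharges —
including repeat and elective admissions — and itself notes that absolute
event counts are overestimated. The synthetic tables emulate that choice,
because the package's comparisons (like the source's) are meaningful
between options, not as absolute burden estimates.

What the generator does **not** emulate: country heterogeneity, births
and migration (the cohort is closed), period trends in mortality or
incidence, and intake differences by age and sex. Passing tests on these
inputs therefore demonstrate the model's structural properties
(conservation, monotonicity, ordering, oracle equivalence), not
calibration to any real national dataset.

## Probabilistic sensitivity analysis

Each of 1000 draws samples every uncertain parameter independently:

* lognormal for the intake relative risk, parameterised from its 95% CI
  (`sigma = (ln 1.37 - ln 1.11)/3.92`, median at 1.23);
* lognormal for the two assumption relative risks (repeat event, repeat-
  event death; SE 20% of the mean, mean-preserving parameterisation);
* gamma for all thirteen cost items by moment matching (SE 20% of the
  mean where only a point value is published);
* one lognormal multiplier (mean 1, CV 10%) per draw for each of the
  life-table, event-probability and case-fatality columns, clamped
  cell-wise to `[0, 1]`; the top age stays absorbing under every draw.
  How table uncertainty was parameterised in the source is not stated;
  a per-table multiplier keeps the draw cost bounded and preserves the
  age gradient, at the price of ignoring cell-level noise.

All four options are rerun with the same parameter set per draw (common
draws), so option contrasts are internally consistent. Draws producing
invalid inputs would be resampled and counted; with the clamped families
above this path is a safety net rather than a regular event. Degenerate
(point-mass) distributions reproduce the deterministic analysis exactly,
and identical seeds give identical results; both are tested.

With the CI-faithful relative-risk lognormal, a draw near RR = 1 produces
almost no CAD savings while the food-inspection programme still costs
money, so the probability that the voluntary option saves costs is
slightly below 1 per draw; across 1000 draws the observed dominance share
for the voluntary and legal-limit arms is typically 99-100%, mirroring
the published near-certain dominance.

## Numerical choices and problem sizes

* Probabilities are the native scale; hazard conversions happen only
  inside the generator and the competing-risk subtraction.
* Transition rows are stochastic to 1e-12; conservation is enforced to
  1e-9 relative; rounding happens only at presentation.
* Ages are integer years 0-100; ties between event and death from Well
  are resolved by capping non-CAD death at `1 - p_first` (the event takes
  precedence in the rare near-saturated stratum).
* The deterministic analysis runs 4 options x 85 cycles x 202 strata in
  well under a second; the full PSA (1000 draws x 4 options) takes about
  a minute. The test-suite microsimulation uses 10,000 people, 20 years
  and 50 replicates; property tests use grids of 5-50 ages.
* CSV round trips are bit-exact: files are written with shortest
  round-trip doubles and read with the correctly-rounded base-R parser.

## Known limitations

* CAD does not compete against other diseases beyond the hazard
  subtraction; absolute event counts inherit the overestimation of the
  discharge-based event probabilities.
* The closed cohort ages out: no births or migration, so late-horizon
  person-years shrink relative to a standing population.
* Measure costs are charged per alive person per year, which ties policy
  cost to cohort survival rather than to a constant administrative
  budget.
* No half-cycle correction; no cost-effectiveness acceptability curves or
  value-of-information analysis (the cost-effectiveness plane and
  dominance probabilities are exported instead).

## A worked example

```{r example, eval = FALSE}
tabs <- generate_inputs(synthetic_config(seed = 1))
inputs <- as_inputs(tabs$life_table, tabs$morbidity, tabs$population,
                    run_config(scenario = "base"))
analysis <- run_deterministic(inputs)
tidy(analysis)        # per-option discounted costs and DALYs
analysis$incremental  # deltas vs reference, ICERs, dominance, CE class

psa <- run_psa(inputs, n_draws = 1000, seed = 1)
glance(psa)           # dominance probabilities per option
autoplot(psa)         # cost-effectiveness plane
```
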