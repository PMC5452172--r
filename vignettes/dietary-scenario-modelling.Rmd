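---
title: "Dietary scenario modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary scenario modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietscen)
```

## The model

`dietscen` is a static, deterministic, discrete-time microsimulation of
population dietary intake. The base case is observed behaviour: one
24-hour recall per person, expanded to the population with survey weights.
A scenario is a deterministic transformation of that base case; the model
makes no claim about uptake, behaviour change dynamics, or prices — it
answers "if intake changed exactly like this, what would the population
nutrient profile look like?"

All quantities are daily per-capita amounts. Composition is stored per
100 g and scaled linearly to consumed grams, which is the only reading
under which per-100 g food-composition tables combine with gram intakes.
Energy is computed from macronutrients with fixed gross factors
(kJ/g): protein 16.736, carbohydrate 16.736, fat 37.656, dietary fibre
8.368, alcohol 29.288. Sugars inherit the carbohydrate factor and fatty
acid classes the fat factor for percent-of-energy reporting only; the
energy sum itself uses the five base components so sugars and fatty acids
are never double-counted.

Foods are classified by survey flags into `core_food`, `core_beverage`,
`discretionary_food` and `discretionary_beverage`. Two conventions
matter downstream:

* **milk as food** — milk-flagged beverages (plain or flavoured) classify
  as core *foods*, on nutrient-profile and consumption-pattern grounds, so
  they sit in the food-substitution pool rather than the beverage pool.
  The rule is a configurable flag (`classify_foods(milk_as_food =)`), with
  membership carried by the `is_milk` column rather than a hard-coded code
  list, because subgroup taxonomies differ between composition databases.
* **sports products and meal replacements** — these carry their own flag
  and are excluded from the *discretionary beverage* reporting class and
  from beverage-targeted scenarios, while still counting as discretionary
  choices overall. This mirrors how survey summary tables footnote them.

## Two execution modes

Every transform runs in two modes:

* **person mode** on a `diet_data` object: intake lines are expanded to
  absolute per-line nutrient amounts (`expand_intake()`), transformed, and
  re-aggregated with the population weights.
* **aggregate mode** on an `aggregate_profile`: a five-row class-level
  table (total, core, discretionary, discretionary foods, discretionary
  beverages) of population means. Published survey tables are exactly this
  shape, so scenario arithmetic can be validated against printed national
  results without restricted microdata; `aus_basecase()` ships the
  Australian adult base case for that purpose.

For the linear transforms (moderation, reformulation) the two modes agree
exactly, and the test suite checks this equivalence by brute force on
synthetic datasets. Aggregate mode has two intrinsic limitations, both
checked and documented rather than hidden: the published core column does
not split foods from beverages, so the energy-compensation pool there
includes core beverages (person mode excludes them); and subgroup-level
replacement ratios are unavailable, so substitution uses the overall
ratio.

A deliberate numerical choice in aggregate mode: published class columns
are independently rounded and do not sum exactly to published totals
(sodium: 1567.1 + 863.5 ≠ 2430.5). Transforms therefore apply *deltas* to
the total row (`total − f × class`) instead of recomputing
`total = core + discretionary`, which reproduces published scenario cells
at printed precision instead of accumulating rounding from two columns.
For the same reason, energy after reformulation is updated by the
density-weighted macronutrient deltas applied to the tracked energy field,
not recomputed wholesale from the (rounded) printed macronutrients; in
person mode the two are identical, and the energy-closure invariant
(recomputed vs tracked energy within 0.5%) is asserted for every profile.

## Scenario parameters

| Parameter | Default | Meaning |
|---|---|---|
| `reduction_fraction` | 0.5 | fraction of targeted discretionary intake removed (moderation, substitution) |
| `compensation_fraction` | 0 (bounds 0.25, 0.75) | fraction of the food-derived energy deficit eaten back |
| `default_ratio` | 1.29 | grams of replacement added per gram removed (overridable per 3-digit subgroup) |
| `beverage_ratio` | 1 | volume-for-volume water/juice replacement of removed beverages |
| `sfa_replace_fraction` | 0.50 (0.25–0.75) | SFA swapped into unsaturated fats, foods only |
| `added_sugar_reduction` | 0.25 (0.10–0.40) | added sugars removed from targeted composition |
| `sodium_reduction` | 0.20 (0.10–0.40) | sodium removed |
| `alcohol_reduction` | 0.25 (0.25–0.50) | alcohol content cut in alcoholic beverages |

Design decisions where the procedure was genuinely open:

* **Moderation as gram scaling.** A "50% reduction in energy from
  discretionary choices" is implemented as proportional gram scaling of
  each targeted item. Item-wise the two are identical (all nutrients of an
  item scale with its energy), and gram scaling keeps every nutrient
  coherent at once.
* **Compensation in base-case proportions.** Compensated energy is
  distributed over the pool (core foods + post-moderation discretionary
  foods, never beverages) pro rata to each item's *base-case* energy,
  i.e. every pool member gains `λ ×` its base-case amount with
  `λ = c·f·E(disc foods) / E(pool)`. Compensation therefore adds nutrients
  only in base-case pool proportions — asserted as an invariant. Beverage
  deficits are never compensated: energy compensation after reduced liquid
  intake is not supported by the feeding literature the parameterisation
  follows.
* **Replacement ratio orientation.** The ratio is defined as *grams added
  per gram removed*: the median per-consumer daily subgroup intake of the
  replacement group divided by that of the removed group (1.29 means
  100 g of discretionary choices are replaced by 129 g of core choices).
  Published subgroup-level ratio tables are not reproducible from class
  means, so the ratio table is an explicit input with the overall value as
  fallback.
* **Within-pool allocation pro rata by base-case gram share**, preserving
  observed eating patterns rather than imposing a uniform or per-capita
  allocation.
* **SFA swap applies to discretionary foods only.** Beverage SFA is
  negligible and published beverage-reformulation results leave SFA
  untouched; applying the swap to the food class also reproduces the
  published all-discretionary SFA sensitivity range to within 0.05
  percentage points, which the choices-level pool does not.
* **Alcohol reduction is removal**, with no carbohydrate back-fill, and
  reformulation mass bookkeeping deducts removed sugar grams, alcohol
  grams and sodium (mg → g) from item weight. With
  `sweetener_replacement = TRUE` the removed sugar is instead assumed
  replaced by an energy- and mass-equivalent bulk sweetener, so only its
  labelled sugar content changes.

## Numerical choices

* Added-sugar removal is clipped so the sugar hierarchy
  (added ≤ free ≤ total ≤ carbohydrate) can never go negative.
* The MUFA:PUFA split of swapped SFA uses the item's current ratio, with a
  50:50 tie-break when both are zero; where a table carries no MUFA/PUFA
  columns (published class means) the unsaturated side is left `NA` and
  total fat is still conserved.
* All arithmetic is at full precision; rounding to one decimal happens
  only in the reporting layer (`format_profile_table()`, printed percent
  changes).
* Composition tables written by the package format numerics at 10
  significant digits, making write–read–write cycles byte-stable.
* Zero-gram intake lines are legal and inert: recall data contain trace
  entries, and dropping them would silently change record counts.

## The synthetic population generator

The generator emulates the structure of a national single-day recall
survey: ~26 archetypal foods spanning all four classes (with alcoholic,
water-based, milk and sports-product flags all exercised), gamma
population weights normalised to mean 1, per-archetype Bernoulli
consumption and log-normal portions. Discretionary beverages are sugar-
and alcohol-dense, discretionary foods SFA- and sodium-dense, and core
choices carry most micronutrient density, qualitatively matching national
nutrient-density contrasts.

Calibration then makes the dataset quantitatively usable as a test
double: within each class (core, discretionary foods, discretionary
beverages) a single multiplicative factor per food is solved so the
weighted class means of grams, energy, SFA, added sugars, sodium and
alcohol hit the published values *exactly*. The factors are the solution
of the linear constraint system minimising gram-weighted deviation from 1,
with an active-set floor at 0.02 to keep all factors positive; infeasible
targets (e.g. energy without mass, no intake in a targeted class) error
before or during calibration rather than silently drifting. Portion-size
parameters (consumer fractions, log-normal scales) were chosen once so
that typical per-consumer subgroup intakes put the discretionary:core
median-intake ratio near the published 1.29, and the test suite checks
that the ratio distribution across seeds brackets that value.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: demographic intake gradients (age/sex structure
is decorative), day-of-week effects, usual-intake (multi-day) variance,
misreporting, and the full 8-digit food-code granularity of a real
composition database (each archetype is its own subgroup). Results on
synthetic data validate the *arithmetic* of the pipeline, not the
epidemiology of any particular population; the published-table aggregate
mode is the bridge to real national results.

Note one structural artefact of published tables that the generator
inherits: the discretionary foods and beverages columns do not sum to the
discretionary-choices column (sports products are footnoted out of the
beverage column, and the printed columns are independently rounded), so a
generated total differs from the printed grand total by under 0.4%,
well inside the generator's 2% contract.

## Problem sizes

Default generator size is 500 persons — large enough that class means are
stable and calibration factors stay near 1, small enough that the full
test suite (property checks on 50–500-person populations, 20-seed ratio
distribution at 150 persons, three 500-person replicates of the energy
contract) runs in well under a minute of compute. All randomness flows
through a single integer seed; identical seed and configuration reproduce
datasets byte-identically.

## Known limitations

* Cross-sectional, single-day intake: no usual-intake correction, no
  longitudinal extrapolation.
* Means only: survey-design variance estimation is out of scope.
* Published beverage-reformulation sodium is not reproducible from class
  means under a flat 20% cut; the subset of beverages actually
  reformulated for sodium in the source analyses is not recoverable, and
  the package applies the stated flat cut.
* Uptake, price/tax elasticities and health-outcome modelling are
  explicitly out of scope; the model compares nutritional endpoints of
  fully adopted strategies.
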