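---
title: "Benefit incidence analysis of public health subsidies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benefit incidence analysis of public health subsidies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biatools)
```

## The problem

Public hospitals charge far less at the point of care than private ones, so
every publicly provided episode of care carries an implicit subsidy. Benefit
incidence analysis (BIA) asks *who captures that subsidy*: when the
subsidies embedded in public inpatient (IP) and outpatient (OP) care for
noncommunicable diseases (NCDs) among the elderly are added up by
socio-economic class, is the distribution pro-poor or pro-rich? `biatools`
implements the full chain from survey-style microdata to that answer:
living-standards classes, utilization and out-of-pocket expenditure (OOPE)
tables, net-subsidy estimation against a private-cost proxy, benefit shares,
and concentration curves and indices with robust inference. A synthetic-data
generator with planted equity structure gives every stage a known ground
truth, because the real microdata of interest (Indian National Sample
Survey-style health rounds) are registration-gated.

## Data model

Four linked tables: households (state, sector, total monthly expenditure
$T$, size $N$, survey multiplier weight), individuals (age, sex), inpatient
episodes (one ailment code, facility, days of stay, itemized OOPE) and
outpatient spells. An outpatient spell covers all visits in a 15-day recall
and carries ONE pooled OOPE for those visits — a structural limitation of
the source surveys that drives the selection rule below. A column-mapping
config adapts arbitrary CSV extracts to this canonical schema, and a
state-recoding table supports clubbing small states and union territories
into pooled codes without any hard-coded geography. Validation
(`validate_survey()`) reports every invariant violation as data rather than
exceptions.

## Stratification

**Living standards.** Monthly per-capita expenditure (MPCE) uses the OECD
square-root equivalence scale, $\mathrm{mpce} = T/\sqrt{N}$, computed per
household. Because price levels differ by state and between rural and urban
areas, quartile cutpoints are computed separately within every (state,
sector) cell, over households, at cumulative weight shares 0.25/0.50/0.75
of the *left-continuous inverse weighted CDF* — the lowest observed value
whose cumulative weight share reaches the probability. No interpolation:
on discrete survey data this definition is exactly reproducible and
interpolated variants differ only at ties. Ties at a cutpoint go *down*
(a household exactly at the first cutpoint is Poorest), so with fully
collapsed cutpoints the degenerate cell collapses into P. Members inherit
their household's class; individuals, not households, are what utilization
counts.

**Disease groups.** Ailment codes partition into communicable (CD),
noncommunicable (NCD) and other (OD) groups via an editable JSON map. The
shipped default map is an illustrative grouping of common survey ailment
labels — the source surveys' own code lists are not public, so users with
real extracts should supply their own. Unmapped codes fall into OD, the
residual group, with a warning.

**Selection.** Elderly means aged 60 and above, inclusive. The NCD
inpatient set keeps episodes whose ailment maps to NCD. Because outpatient
OOPE is pooled across a spell's visits, a spell is kept only when *every*
visit's ailment maps to NCD; one non-NCD visit excludes the spell entirely
(otherwise non-NCD spending would contaminate the NCD OOPE). For the
descriptive ailment-group panel, a multi-visit spell with mixed groups is
assigned to the residual OD group. Inpatient episodes carry a single
ailment code by design; surveys that record several per hospitalization
must be reduced to a primary code upstream.

## Descriptive tables

Utilization shares are survey-weighted percentages per episode/spell, in
three panels (ailment groups among all elderly episodes; class shares among
elderly NCD episodes; class shares among public-facility elderly NCD
episodes), with columns summing to 100 within each (panel, service,
sector). OOPE decomposes cumulatively — medicine; medical = medicine +
other medical care; total = medical + transport + other non-medical — so
`medicine <= medical <= total` holds in every cell by construction. The
"combine" sector always pools rural and urban records; it is never an
average of the two columns.

## The subsidy model

The cost of serving a patient in a public facility is unobserved. Following
the BIA literature the package proxies it by the **modal private-sector
total OOPE** in the matching stratum: state × sector × MPCE class ×
duration band, separately per service. The stratification absorbs regional
prices, quality and severity (duration of stay / of ailment is the severity
proxy). The mode of a continuous variable is undefined without a
convention, so it is defined by fixed-width binning: totals fall in
half-open bins of width 500 INR (IP) or 50 INR (OP), the modal cost is the
weighted-count-maximizing bin's weighted mean of member values, and ties
break toward the lower bin — deterministic, documentable, and recoverable
in simulation. Strata with fewer than `min_cell_size = 5` private episodes
pool up the fallback ladder `full → drop_duration → drop_class →
drop_state → global`, recording the pooling level used; the band edges
(IP 1–3/4–7/8–14/15+ days, OP 0–14/15–30/31–90/91+ days), bin widths,
ladder and cell size are conventions of this package, configurable, since
the methodology literature fixes none of them.

The **net subsidy** of a public episode is
$\gamma_k = \text{modal cost}(\text{stratum}_k) - \text{OOPE}_k$, clamped
at zero by default (a subsidy cannot be negative under the proxy's own
logic); the clamp count is reported and a toggle preserves the literal
subtraction. With utilization rates
$\delta_j = \sum_{k \in j} w_k / \sum_k w_k$ over public episodes, the
class benefit is

$$\pi_j = \delta_j \sum_{k \in j} w_k \gamma_k,$$

and the benefit-incidence estimate is each class's percentage share of
$\sum_j \pi_j$. Note the $\delta_j$-weighting counts utilization twice
relative to plain subsidy sums — that is the formula as used in this
strand of the BIA literature, and it is implemented as such; an
`rate_weighted = FALSE` variant gives the plain subsidy-sum shares for
sensitivity analysis. The sum in $\pi_j$ runs over the members of class
$j$ (the prose reading "add all the individual subsidies of a class"),
not over all individuals.

## Concentration curves and indices

The health variable is the public subsidy itself: $h_k = \gamma_k$ over
public-facility elderly NCD episodes (the population whose counts appear
in the index table), ranked by the individual's *continuous* equivalized
MPCE. Ranking by the 4-level class is available (`rank = "class"`) but a
4-level rank makes micro indices ill-defined at ties, so continuous is the
default; ties break by a stable record key, spreading tied blocks
uniformly. With normalized weights $\tilde w$, fractional ranks
$r_i = \sum_{j<i}\tilde w_j + \tilde w_i/2$ and $\mu$ the weighted mean of
$h$:

$$C = \frac{2}{\mu}\sum_i \tilde w_i (h_i - \mu)(r_i - \bar r),$$

which equals twice the signed area between the concentration curve and the
45° equality line (negative = curve above the line = pro-poor). Inference
uses the convenient regression: WLS of $2\sigma_r^2 h_i/\mu$ on $r_i$,
whose slope is algebraically identical to $C$; the standard error is
heteroskedasticity-robust (HC1) by default, or household-clustered via
`se = "cluster"` (the index table of the motivating application reports
only "robust" errors, so HC1 is the default and clustering is a flag),
with $t_{n-2}$ p-values. For grouped data (four class shares), the grouped
formula $C = \sum_t (P_t L_{t+1} - P_{t+1} L_t)$ on cumulative population
and benefit shares applies; it equals the micro index when the benefit is
group-constant and groups are contiguous in rank. Curve confidence bands
resample *households* with replacement (the natural cluster unit; the
multistage survey design's primary sampling units are not modeled),
recomputing the curve on a fixed 101-point grid, with pointwise 2.5/97.5
percentiles; deterministic given a seed.

## The synthetic-data generator

`simulate_survey()` emulates the features of the real setting that the
pipeline is sensitive to: a state × sector household frame; lognormal
household expenditure (rural level below urban, per-state shifts); survey
multiplier weights drawn `U(0.5, 2) × 100` per household, independent of
expenditure, so weighted and unweighted estimands differ detectably but
boundedly; household size `1 + Poisson`, mean 4.3; an 8.2% elderly share
with age-graded NCD morbidity (logit intercept −4.5, slope 0.055/year:
prevalence ≈ 23% at 60, ≈ 47% at 80); facility choice by a logit with
planted gradient `g` (log-odds of private per class step, default 0.4,
pro-private among the rich); inpatient stay `1 + Geometric(0.17)` and
outpatient duration `Gamma(1.3, 55)` days, giving all four duration bands
substantial mass; and per-stratum private cost locations
`base × state × class-ratio × band` with rural IP base 15,000 INR, urban
20,000, OP 550/750, class ratio 1.15 per step, band multipliers 0.7–2
(IP). Public OOPE is lognormal with mean 35% of the stratum's private
location, so public sits systematically below private everywhere. These
defaults were chosen once as a plausible Indian-survey-scale world and are
the conditions under which all tests run.

**Mode-recoverable costs.** Private totals are *shifted lognormal
re-parameterized by the mode*: `total = location − d + Y` with `Y`
lognormal of mode `d` (2,500 INR IP, 250 OP; log-sd 0.35). The shift gives
the within-stratum noise a fixed absolute scale, so the planted mode is
equally identifiable in a 10,000-INR and a 45,000-INR stratum with the
same 500-INR bins — a deliberate design: a multiplicative spread makes the
density top so flat at high cost levels that no histogram-mode estimator
can localize it at feasible sample sizes. The price is that within-stratum
cost dispersion is tighter than real OOPE data; what passing
modal-recovery tests demonstrate is therefore the estimator's correctness
on a well-posed target, not its precision on arbitrarily dispersed costs.

**Ground truth.** The generator returns, alongside the dataset, the planted
stratum cost locations, each household's true class, per-episode true
subsidies (true location minus the drawn public OOPE, floored at zero),
class benefit shares by the $\pi_j$ formula, and a true grouped
concentration index. The truth's population shares are the classes'
planted weight shares of the *recipient* population (the public elderly
NCD episodes), not fixed quarters: equivalized MPCE is mechanically
anti-correlated with household size, so poorer classes contain more people
and more episodes per household quartile, and a fixed-quarters grouped
index would not be the estimand of any episode-level statistic — a fully
neutral configuration would show a spuriously pro-poor "truth". With
recipient shares, the truth is exactly the grouped analogue of the micro
index the pipeline estimates.

## Recovery experiment design

The validation suite uses three planted worlds, all on a single-state,
two-sector frame (the simplest frame in which the class machinery is fully
exercised; multi-state structure is tested separately):

* **Share recovery** — facility gradient `g = 0.4`, ≈ 20,000 elderly NCD
  episodes, 3 seeds: estimated class benefit shares must sit within 3
  percentage points of the planted shares with every stratum estimable at
  the full pooling level (observed errors ≈ 1 pp).
* **Index recovery** — class cost gradient 1.15 with `g = 0`, per-sector
  evaluation, 20 seeds: the estimated index must lie within 2 robust SEs
  of the planted grouped index in ≥ 18 seeds. `g = 0` keeps utilization
  class-balanced, which is the regime in which the episode-level index and
  the class-level grouped truth estimate the same quantity; with `g ≠ 0`
  they are genuinely different estimands (the recipient population's class
  composition shifts), so a mismatch there would be a property of the
  estimands, not an estimator defect. Per-sector evaluation avoids the
  analogous cross-sector twist: pooling rural and urban mixes different
  cost bases with different expenditure levels.
* **Power and null** — at the ≈ 5,000-episode scale of the published index
  tables: with the pro-rich world planted, the index is positive with
  p < 0.05 in ≥ 18/20 seeds; with *nothing* planted (`g = 0`, class cost
  ratio 1), |C| < 0.02 with p > 0.05 in ≥ 17/20 seeds.

## Numerical conventions and degenerate inputs

Quantiles never interpolate; class ties go down; modal bins tie to the
lower bin; a constant benefit yields index 0 with p = 1 (a zero-residual
regression is treated as no evidence, not 0/0); a zero-subsidy cell yields
missing shares with a warning rather than NaNs; empty utilization
universes warn and omit the panel; blank OOPE cells load as zero with a
warning (survey extracts commonly blank zero cells) while negative cells
are validation errors; the global pooling level always resolves, so every
public episode's stratum is priceable whenever any private episode exists
for the service — if none does, the proxy is undefined and the pipeline
stops.

## Known limitations

* The modal-cost proxy equates public provision cost with private modal
  OOPE; systematic public/private cost differences shift subsidy *levels*,
  though class *shares* are less affected (the proxy's usual defense).
* The index's robust SE conditions on the estimated modal-cost table. At
  small per-stratum counts (tens of private episodes) the binned-mode
  estimator contributes class-level noise the nominal SE cannot see, so
  null rejection rates run slightly above nominal; household clustering
  does not fix this because the noise is shared across households within
  a stratum.
* The generator does not simulate multistage cluster sampling (episodes
  are independent given strata), calibration to real survey marginals, or
  within-NCD heterogeneity; passing tests say nothing about those
  features of real data.
* No quintile/decile classes: with realistic elderly-NCD sample sizes the
  four-class design is already near the sparsity limit of the stratified
  modal proxy.
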