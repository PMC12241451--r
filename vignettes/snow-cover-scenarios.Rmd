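---
title: "Modelling snow-cover loss for an overwintering wetland snail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling snow-cover loss for an overwintering wetland snail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertigopop)
```

## The model and its assumptions

`vertigopop` implements a deterministic, discrete-time, age-structured
model for *Vertigo moulinsiana*, a minute freeze-avoidant wetland snail.
The population is divided into five stages: eggs `E`, juveniles `J`, and
adults in three age classes — `N1` (matured this season, before their
first overwintering), `N2` (after one overwintering) and `N3` (after
two). A modelled year is a *season* of six monthly steps (May–October,
the species' activity window, `i = 1..6`), and the whole November–April
winter is compressed into a single overwintering transition. This
coarse calendar matches the biology: the snail neither lays nor grows
outside the activity window, and overwinter mortality acts once.

Within a season the updates are, in order, for each month `i >= 2`:

* juveniles: `J(i) = J(i-1) d_j + E(i-1) d_e`, with two structural
  exceptions — `J(1) = 0` (every juvenile that survives the winter
  matures) and `J(2) = E(1) d_e` (the season's first hatch);
* in months 5 and 6, the cohort hatched three months earlier (the mean
  time to maturity is roughly three months, 99 days) reaches maturity;
  `a J(i-3) d_j` newly matured adults join `N1`;
* adults: `N1(i) = N1(i-1) d_a1 (+ recruitment)`, `N2(i) = N2(i-1) d_a2`,
  `N3(i) = N3(i-1) d_a3`;
* laying: `E(i) = N1(i) e1(i) + N2(i) e2(i) + N3(i) e3(i)`, with
  `e3 = 0` by default (age-3 adults are carried in the structure but do
  not lay under the default schedules).

Between seasons, `overwinter()` applies the winter survival `d_w` to
juveniles and all adult classes, advances each class by one
overwintering (`J -> N1 -> N2 -> N3`), removes age-3 adults (no fourth
class exists) and discards unhatched eggs — egg overwintering has not
been observed in this species. Eggs laid in month 6 therefore never
hatch: hatching uses the previous month's eggs and month 1 has no hatch
branch, mirroring a June–September hatching window.

All abundances are expected counts (real-valued); every update is linear
in the state, so the model propagates expectations exactly and scale
never matters for growth rates or scenario orderings. There is no
density dependence, no environmental stochasticity in the core, no
spatial structure, and a single mortality parameter per stage.

### The two maturation bookkeeping modes

As printed, the juvenile update in months 5–6 subtracts
`(1 - a) J(i-3) d_j` while the adult update adds `a J(i-3) d_j`: the
*whole* lagged cohort leaves the juvenile pool even though only the
fraction `a` (10–15 %) matures in its season of hatching and the
remainder is described as maturing the following season. Whether this is
intended or a typographical slip cannot be decided from the equations
alone, so both are shipped:

* `mode = "literal"` (default) — exactly the printed rule; required to
  reproduce the published scenario tables;
* `mode = "corrected"` — subtracts only the maturing fraction
  `a J(i-3) d_j`, so non-maturing juveniles remain to overwinter.

In literal mode a negative intermediate is possible when the lagged
cohort is large relative to current hatching; it is clamped to zero and
logged with step coordinates in the result's `diagnostics` (never
silently), since a silent clamp would mask exactly this ambiguity. With
`a = 1` the two modes coincide. A related consequence of the printed
branches: juveniles present in a user-supplied season-1, month-1 state
exist for that month only (the month-2 branch is hatching-only), which
is why model-generated month-1 states always carry `J = 0`.

## Parameters

| Parameter | Meaning | Default | Source of the default |
|---|---|---|---|
| `d_a1`, `d_a2`, `d_a3` | monthly adult survival | 0.875 | midpoint of the reported 10–15 % monthly adult mortality |
| `d_j` | monthly juvenile survival | 0.85 | **placeholder, not text-derived** |
| `d_e` | egg hatching ratio (month-to-month) | 0.8 | **placeholder, not text-derived** |
| `d_w` | winter survival | 0.7 | within the observed 0.60–0.73 |
| `a` | same-season maturation fraction | 0.125 | midpoint of the reported 10–15 % |
| `e1`, `e2` | monthly per-capita laying, May–October | (4.75, 4.75, 4.75, 4.75, 0, 0) | 19 eggs per season laid May–August, spread uniformly |
| `e3` | age-3 laying | zero vector | age-3 laying appears in the life-cycle structure but not in the laying equation |

No published value exists in the text for `d_j` and `d_e`; the defaults
keep the package runnable and are flagged in `?default_parameters`, and
a calibrated set can be injected verbatim through the YAML config
(`load_config()`). The uniform May–August laying shape is likewise a
choice — only the seasonal total (19) and the window are reported — and
alternative shapes are configurable. Because absolute abundances depend
on these placeholders, the package's tests assert *relations* (ordering,
monotonicity, linearity, branch arithmetic), not published absolute
population sizes.

The default initial state (100 individuals in each of `J`, `N1`, `N2`,
`N3`) is arbitrary; linearity makes the growth rate and all scenario
orderings independent of it.

## From supercooling points to winter mortality

A freeze-avoidant snail dies when the ambient temperature reaches its
supercooling point (SCP). Without the insulating subnivium, a winter
minimum `t_min` therefore kills the fraction of the population whose SCP
is at or above `t_min` (`mortality_from_scp()`; ties count as freezing).
Freeze mortality then acts on top of baseline overwintering mortality:

```{r}
adjust_winter_survival(0.7, 0.50)
```

The multiplicative form `d_w_base (1 - m)` is the only simple rule
consistent with all four published adjusted values (0.7·0.97 → 0.68,
0.7·0.77 → 0.54, 0.7·0.50 = 0.35, 0.7·0.05 → 0.04, at two decimals,
half-up). Internal values are never rounded; `round2()` rounding is
applied only when comparing against printed two-decimal values, with a
`1e-9` guard because `0.7 * 0.05` sits on a binary representation
boundary.

`build_paper_scenarios()` returns the five canonical scenarios —
baseline "0" plus winter minima of −5.5, −8, −10 and −14 °C with
published freeze mortalities 3, 23, 50 and 95 %. The published pairs are
taken as authoritative rather than re-derived from an SCP histogram;
note they are internally tense (95 %, not 100 %, at the sample minimum
−14 °C, and 3 % at −6 °C although the reported maximum SCP is −6.3 °C),
so the SCP-sample route is intended for new analyses, the direct
fractions for reproducing the published scenarios.

## The synthetic SCP generator

`synthetic_scp_sample()` draws from a piecewise-linear quantile function
through the anchors (0, −15), (0.05, −14), (0.50, −10), (0.77, −8),
(1, −6.3): support equal to the reported range and freezing fractions of
95/50/23 % at −14/−10/−8 °C. The −6 °C/3 % pair is unrealisable given a
−6.3 °C maximum and is deliberately not anchored. The implied
distribution mean is about −10.2 °C against a reported sample mean of
−9.9 °C — acceptable for a generator whose calibrated quantities are the
threshold fractions, and documented rather than tuned away. Sampling is
systematic: one uniform per probability stratum of width `1/n`, then a
seeded shuffle, so every empirical threshold fraction lands within `1/n`
of its anchor *by construction* (at `n = 200`, within 0.5 percentage
points). Seeds are applied in a scoped way that restores the caller's
RNG state.

What the generator does **not** emulate: stage-specific SCP differences
(the data motivating a juvenile/adult tag report no significant
difference and print no stage-resolved values), between-winter
acclimation, or measurement error. Passing calibration tests therefore
show that the scenario machinery converts a *given* SCP distribution
correctly, not that the synthetic distribution is the species' true one.

## The individual-based cross-check

`ibm_oracle()` simulates whole individuals under the same per-capita
rules: binomial survival for every class, Poisson egg counts with the
scheduled per-capita mean (the model fixes only means; Poisson is the
documented counting choice), binomial hatching, and an explicit
lagged-cohort draw in months 5–6 — `D ~ Bin(J(i-3), d_j)` lagged
survivors of which `A ~ Bin(D, a)` mature, with juveniles losing `D - A`
(literal) or `A` (corrected). Expectations match the deterministic
update branch by branch, including the printed equations'
double-counting of the lagged cohort, so replicate means converge on the
deterministic trajectory with standard errors shrinking as `1/sqrt(R)`.
The equivalence test uses 10^4 individuals per class, 200 replicates and
2 seasons, and requires agreement within three Monte-Carlo standard
errors per month.

## Scenario summaries and numerical choices

* **Quasi-extinction**: the deterministic model never hits exactly zero
  from positive states with positive survivals, so extinction is
  declared at the first monthly step whose total falls below 1
  individual *and stays below it* for the rest of the run (transient
  within-season dips do not count). The threshold is configurable.
  Months are active-month steps, six per season: 120 steps for a
  20-season run.
* **Final-season SD**: the sample standard deviation (n − 1) of the six
  monthly totals of the last season — the only within-run spread a
  deterministic model offers.
* **Growth rate** `lambda_growth()` is the plain percent change between
  first- and last-season means, not annualised; it is undefined (NA with
  a warning) when the first-season mean is zero.
* **Sensitivity** `sensitivity_oat()` perturbs each scalar rate by ±10 %
  (clipped to [0, 1] with a warning), and reports central-difference
  elasticities; an `init_scale` pseudo-parameter documents the linearity
  of the model (elasticity exactly 1).
* **Configuration**: one YAML dialect; unknown keys are rejected with
  the offending path named, every applied default is reported, and all
  on-disk numeric output is written at full precision (17 significant
  digits) so CSV round trips are exact.

Default problem sizes — 20 seasons for scenario tables, 6–12 seasons for
property checks, 200 replicates for the stochastic cross-check — resolve
every quantity of interest for this linear model; larger runs change
nothing but runtime.

## Known limitations

The model inherits the simplifications of its construction: constant
parameters across the whole run (so a winter scenario is a *persistent*
regime, not a one-off event), no density dependence (growth is
exponential, so absolute long-run abundances under favourable parameters
are not meaningful, only comparisons), no causes of mortality, no
dispersal or spatial rescue. Scenario conclusions are comparative —
orderings, extinction times, sign of growth — and those are exactly the
quantities the test suite pins down.
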