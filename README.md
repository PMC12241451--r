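# vertigopop

Deterministic, stage-structured population dynamics for the land snail
*Vertigo moulinsiana*, and the demographic consequences of losing winter
snow cover.

*V. moulinsiana* is a minute, vulnerable wetland snail of Central Europe.
It is active from May to October, overwinters as juveniles and adults
(never as eggs) in the thermally buffered *subnivium* — the space at the
snow–ground interface — and avoids freezing by supercooling: an
individual dies when the ambient temperature reaches its supercooling
point (SCP). When snow cover disappears while sub-zero air temperatures
persist, overwintering snails are exposed to winter minima that reach
into the SCP distribution of the population, and winter mortality rises
sharply. `vertigopop` is for population ecologists and conservation
planners who want to quantify that risk.

## The model

Five life stages — eggs `E`, juveniles `J`, and adults `N1`, `N2`, `N3`
at age classes 1, 2, 3 (before the first, after one, and after two
overwinterings) — evolve over six monthly steps per season
(`i = 1..6`, May..October, season `j`), joined by a single aggregated
overwintering transition:

- **Laying** `E(i,j) = N1(i,j) e1(i) + N2(i,j) e2(i)` (age-3 laying
  `e3` is supported but zero by default).
- **Hatching and juvenile survival**
  `J(i,j) = J(i-1,j) d_j + E(i-1,j) d_e`, with `J(1,j) = 0` and
  `J(2,j) = E(1,j) d_e`; in months 5–6 the cohort hatched three months
  earlier matures and a lagged term `(1 - a) J(i-3,j) d_j` leaves the
  pool (literal bookkeeping; a corrected mode that removes only the
  maturing fraction `a J(i-3,j) d_j` is available).
- **Adults** `N1(i,j) = N1(i-1,j) d_a1 [+ a J(i-3,j) d_j in months 5-6]`,
  `N2` and `N3` by survival alone.
- **Overwintering** `N1(1,j) = J(6,j-1) d_w`, `N2(1,j) = N1(6,j-1) d_w`,
  `N3(1,j) = N2(6,j-1) d_w`; age-3 adults and unhatched eggs are removed.
- **Total** `N(i,j) = J + N1 + N2 + N3` (eggs excluded).

A winter minimum `t_min` without snow cover kills the fraction of the
population whose SCP lies at or above `t_min`, and winter survival is
adjusted multiplicatively: `d_w = d_w_base * (1 - mortality)`. Scenario
runs are summarised by the final-season mean/SD/min/max of the monthly
totals, the time to quasi-extinction (first sustained drop of the total
below one individual), and the seasonal growth rate
`lambda = (N_mean_last - N_mean_first) / N_mean_first * 100%`.

## Worked example

```r
library(vertigopop)

# the five canonical snow-loss scenarios and their adjusted winter survival
sapply(build_paper_scenarios(), function(s) s$d_w)
#>     0     1     2     3     4
#> 0.700 0.679 0.539 0.350 0.035

tab <- run_paper_scenarios(n_seasons = 20)
tab[, c("scenario", "t_min", "mortality", "d_w", "mean_final",
        "time_to_extinction_months", "lambda_pct")]
#>  scenario t_min mortality   d_w mean_final time_to_extinction_months lambda_pct
#>         0    NA      0.00 0.700  8.810e+06                        NA  747700.00
#>         1  -5.5      0.03 0.679  4.939e+06                        NA  419100.00
#>         2  -8.0      0.23 0.539  6.142e+04                        NA    5113.00
#>         3 -10.0      0.50 0.350  1.680e+01                        NA     -98.57
#>         4 -14.0      0.95 0.035  1.680e-18                        19    -100.00
```

Scenario "0" keeps intact snow cover (`d_w = 0.7`); scenarios 1–4 expose
the population to winter minima of −5.5, −8, −10 and −14 °C. Under the
text-derived default parameters (see `?default_parameters`; the juvenile
survival and hatching ratio are documented placeholders, so absolute
abundances are illustrative) the ordering is strict: colder snowless
winters always give smaller final populations, negative growth from
scenario 3 on, and quasi-extinction in scenario 4 at month 19 — the opening of season
4, counted in active months (six per season).

The SCP machinery works from measurements:

```r
scp <- synthetic_scp_sample(200, seed = 1)   # calibrated synthetic sample
summary(scp)
#>          n       mean     median        min        max
#> 200.000000 -10.200363 -10.007049 -14.926551  -6.328931
mortality_from_scp(scp, -10)
#> [1] 0.5
adjust_winter_survival(0.7, 0.5)
#> [1] 0.35
```

A stochastic individual-based simulator (`ibm_oracle()`) applying the
same per-capita rules cross-validates the deterministic core, and
`sensitivity_oat()` gives one-at-a-time elasticities. A thin CLI wraps
it all:

```sh
Rscript inst/cli/vertigopop.R paper-scenarios --out results/
Rscript inst/cli/vertigopop.R simulate --config inst/extdata/paper_scenarios.yaml --out results/
Rscript inst/cli/vertigopop.R fixtures --out fixtures/ --seed 5
```

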