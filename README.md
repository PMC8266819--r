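# isodiet

Seasonal diet reconstruction from stable isotopes of sectioned hair.

`isodiet` is an R package for wildlife ecologists who want to turn
non-invasively collected hair samples into quantitative, seasonal,
individual-level estimates of the assimilated diet. It was built around the
analysis of an endangered brown bear population, but the machinery applies
to any species whose hair (or vibrissa/feather) archives diet sequentially:
δ13C and δ15N are measured on consecutive 15-mm hair sections, each section
is assigned to a calendar month via a growth model (15 mm ≈ 1 month, single
annual moult), and the sections of each dietary season are analysed with a
Bayesian stable isotope mixing model (SIMM).

## The model

A consumer section with diet proportions $p = (p_1,\dots,p_K)$ over $K$
food sources has expected isotope value (per tracer $e \in \{^{13}C,
^{15}N\}$)

$$\mu_e(p) = \frac{\sum_k p_k\, q_{ke}\, (\delta_{ke} + \Delta_{ke})}
{\sum_k p_k\, q_{ke}}$$

where $\delta_{ke}$ is the source mean, $\Delta_{ke}$ the trophic
enrichment factor (TEF) of the source's trophic class, and $q_{ke}$ the
source's digestible elemental concentration (so proportions measure
assimilated element fluxes). Observations are normal around $\mu_e(p)$ with
variance = propagated source + TEF process variance + residual variance.
Compositions are regressed on covariates through the isometric log-ratio
(ILR) transform: fixed effects for sex and management status, individual
random effects for bear identity, in seven candidate structures (Null, Sex,
Status, BearID and their combinations). Prior diet knowledge (e.g. scat
EDEC%) enters as an informative Dirichlet prior on the baseline
composition. Fitting uses an adaptive Metropolis-within-Gibbs sampler
(C++); consumers are pre-screened with simulated mixing polygons; competing
structures are compared with PSIS-LOO, its standard errors and Akaike
weights, selecting models with weight > 0.2.

A full methods account is in the vignette:
`vignettes/diet-reconstruction.Rmd`.

## Worked example

Every stage runs on a fully synthetic study generated by the package
itself (27 bears, realistic per-season section counts, sources matching the
packaged key-food table exactly), so the example is reproducible offline.

```r
library(isodiet)
library(dplyr)

# 1. Sources: pool the packaged species-level key-food table
cats <- pool_category_stats(key_food_species())
cats |> select(category, n, mean_d13C, sd_d13C, mean_d15N) |> print(digits = 3)
#> # A tibble: 8 × 5
#>   category                     n mean_d13C sd_d13C mean_d15N
#>   <chr>                    <int>     <dbl>   <dbl>     <dbl>
#> 1 C4                           3     -11.9    0.4      4.3
#> 2 Cultivated fleshy fruits    16     -27.2    1.42     0.575
#> 3 Cultivated vegetables       12     -28.5    1.45     9
#> 4 Formicidae                  26     -26.6    1.2      1.7
#> 5 Hard mast                   18     -27.6    1.60    -1.2
#> 6 Herbs                       63     -30.1    1.61    -2.21
#> 7 Ungulates                    7     -25.3    1.37     4.27
#> 8 Wild fleshy fruits          46     -27.8    1.57    -2.63

# 2. A synthetic study + chronology
scn   <- generate_scenario(scenario_config(seed = 42))
chron <- build_chronology(scn$hairs, scn$sections) |>
  left_join(scn$bears, by = "bear_id") |>
  filter(is.na(exclusion_reason))
count(chron, season)
#> # A tibble: 4 × 2
#>   season           n
#>   <chr>        <int>
#> 1 autumn          26
#> 2 early_summer    61
#> 3 late_summer     55
#> 4 spring          54

# 3. Polygon screening, then fit two structures to the spring sections
space  <- build_mixing_space(aggregate_sources(scn$sources))
spring <- filter(chron, season == "spring")
poly <- simulate_mixing_polygons(
  space, transmute(spring, consumer_id = paste0(sample_id, ":", section_index),
                   d13C, d15N), seed = 1)
sum(poly$excluded)
#> [1] 0

st <- mcmc_settings(chains = 3, iter = 30000, burn = 20000, thin = 10)
fits <- list(
  Null   = fit_simm(spring, space, "Null",   settings = st, seed = 1),
  BearID = fit_simm(spring, space, "BearID", settings = st, seed = 2))
compare_models(fits)
#> # A tibble: 2 × 7
#>   model  looic se_looic delta_looic se_delta weight selected
#>   <chr>  <dbl>    <dbl>       <dbl>    <dbl>  <dbl> <lgl>
#> 1 BearID  327.     14.6        0        0     0.784 TRUE
#> 2 Null    329.     15.7        2.58     3.58  0.216 TRUE

tidy(fits$BearID) |> arrange(desc(mean)) |> print(digits = 2)
#> # A tibble: 7 × 6
#>   level      source                     mean     sd conf.low conf.high
#>   <chr>      <chr>                     <dbl>  <dbl>    <dbl>     <dbl>
#> 1 population Herbs                    0.356  0.0714  0.214       0.491
#> 2 population Hard mast                0.176  0.116   0.00867     0.432
#> 3 population Wild fleshy fruits       0.170  0.122   0.00645     0.443
#> 4 population Cultivated fleshy fruits 0.106  0.0989  0.00187     0.359
#> 5 population Formicidae               0.0754 0.0449  0.00608     0.169
#> 6 population Ungulates                0.0661 0.0445  0.00332     0.166
#> 7 population Cultivated vegetables    0.0507 0.0325  0.00363     0.120
```

The bear random effect is preferred (lowest LOOic, weight 0.78; the null
model's weight 0.22 also clears the 0.2 selection rule, honestly reflecting
how little 54 sections say about a 2.6-unit LOOic gap). The posterior
population diet puts herbs at ~36% of the assimilated spring diet — the
generating truth is 0.35 — with every true proportion inside its 95%
credible interval. `autoplot(fits$BearID)` draws the interval plot;
`tidy(fits$BearID, level = "bear")` gives per-bear diets.

The same stages run end to end from CSV files + a YAML/JSON config via
`run_pipeline(config, out_dir)` (see `?validate_config` for the schema), or
from a shell through the thin wrapper `inst/scripts/isodiet`
(`simulate` / `run` / `validate` subcommands).

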