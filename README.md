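# socsel

Quantifying the spatial scale of social context in sexually polymorphic
plant populations, and what it implies for multilevel (social) selection.

In gynodioecious species, females and hermaphrodites coexist in one
population, and a plant's fitness depends on the sexes around it: a female
ringed by females is pollen-limited, a hermaphrodite ringed by
hermaphrodites competes to sire seeds. Whether that matters
evolutionarily hinges on the covariance between an individual's sex and
the sex ratio of its neighborhood, and on the spatial scale over which
"neighborhood" is defined — typically the scale of pollinator movement.
`socsel` is for field ecologists and evolutionary biologists who have (or
want to simulate) mapped, sexed populations and want to ask: *at what
scale does social context vary, and how strong would social selection have
to be to matter?*

## The model

The total selection differential on a trait decomposes as

```
S_i = P_ii * beta_N  +  C_ij' * beta_S
```

where `P_ii` is the focal-trait variance, `beta_N` the nonsocial (direct)
selection gradient, `C_ij'` the covariance between an individual's trait
(sex, hermaphrodite = 1) and the mean trait of its social partners (the
local hermaphrodite frequency, focal plant excluded), and `beta_S` the
social selection gradient. `C_ij' = 0` means neighbors exert no net
selection; `C_ij' > 0` means own-sex-biased neighborhoods, which
exacerbate pollen limitation in females. The package measures `C_ij'`
and the variance of local sex ratio across a nested grid of radii
(default 0.5–6.0 m), and inverts the model for the *critical social
gradient* `beta_S* = -S_N / C_ij'` at which social selection exactly
cancels the fecundity advantage of females.

The pipeline covers: trilateration of range-finder surveys into planar
maps; per-plant neighborhood sex-ratio profiles at nested radii; scale
summaries, Brown–Forsythe heterogeneity-of-variance tests, a sex-by-scale
binomial GLM, cross-scale correlation matrices; `C_ij'`/`P_jj` covariance
profiles under two standardizations with a label-permutation null; the
selection arithmetic; and a Thomas-cluster synthetic population generator
with spatially autocorrelated sex labels so everything is testable without
field data.

## Worked example

```r
library(socsel)

cfg <- synth_config(seed = 42)      # field-calibrated defaults, ~320 plants
pop <- generate_population(cfg)
population_summary(pop)
#>   population_id     n n_hermaphrodite herm_frequency
#> 1 synth           378             252          0.667

prof <- neighborhood_profiles(pop)  # plant x radius local sex ratios
scale_summary(prof)
#>   radius mean_freq var_freq mean_neighbors n_defined n_plants
#> 1    0.5     0.655   0.127            2.77       320      378
#> 2    1       0.666   0.0699          10.5        373      378
#> 3    1.5     0.659   0.0457          21.9        378      378
#> ...
```

The variance of the locally experienced sex ratio collapses with radius
(0.127 at 0.5 m to below 0.01 at 6 m here): nearest neighbors define
wildly different social worlds, stand-level context is nearly uniform.
The heterogeneity is testable, and the sex/context covariance has a
permutation null:

```r
brown_forsythe(prof)
#> Brown-Forsythe (ANOVA on |x - group median|)
#> F = 86.6902, df = (11, 4461), p = 2.004e-178  [12 groups, 4473 values]

covariance_profile(prof)
#>   radius n_defined  C_raw  P_ii   P_jj C_std_cor C_std_pii
#> 1    0.5       320 0.0649 0.225 0.127      0.384     0.288
#> 2    1         373 0.0408 0.223 0.0699     0.327     0.183
#> ...

permutation_null(pop, radius = 0.5, n_perm = 999, seed = 1)
#> Permutation null for C_std (correlation convention) at r = 0.5 m
#> observed = 0.3840, p = 0.001 (999 permutations, 320 plants with neighbors)
```

Plants are significantly surrounded by their own sex at 0.5 m. Feeding a
fecundity scheme (default: females set twice the seed of hermaphrodites)
through the selection module turns the covariance profile into threshold
curves:

```r
s_n <- natural_selection_differential(mean(sex_code(pop$sex)))
s_n
#> [1] -0.3536                      # direct female advantage, standardized

selection_thresholds(covariance_profile(prof), s_n, convention = "pii")
#>   radius C_std beta_S_star ratio_vs_smallest
#> 1    0.5 0.288        1.23              1
#> 2    1   0.183        1.94              1.58
#> ...
```

Read: if pollen moves among nearest neighbors (0.5 m), a social gradient
of ~1.2 would cancel the females' twofold seed advantage; if it moves at
meters-plus scales the required gradient grows several-fold, because the
covariance that social selection needs has evaporated. Plot methods
(`plot_population()`, `plot_scale_variance()`, `plot_covariance_profile()`,
`plot_thresholds()`, `autoplot()` on test objects) draw each of these
surfaces.

With real survey files the front end is:

```r
st  <- readr::read_csv("stations.csv")          # station_id, latitude, longitude
sv  <- readr::read_csv("survey.csv")            # plant_id, sex, d1, d2, d3
pop <- trilaterate_all(sv, project_stations(st))
```

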