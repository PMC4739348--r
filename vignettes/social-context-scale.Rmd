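---
title: "Scale-dependent social context and social selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-dependent social context and social selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(socsel)
library(dplyr)
```

## The model

In a sexually polymorphic population, an individual's fitness can depend not
only on its own sex but on the sexes of the plants around it: a female
surrounded by females competes for scarce pollen, a hermaphrodite surrounded
by hermaphrodites competes to sire seeds. Multilevel (social) selection
theory decomposes the total selection differential on a trait into

$$S_i = P_{ii}\,\beta_N + C_{ij}'\,\beta_S,$$

where $P_{ii}$ is the phenotypic variance of the focal trait, $\beta_N$ the
nonsocial (direct) selection gradient, $C_{ij}'$ the covariance between an
individual's trait value and the mean trait of its social partners, and
$\beta_S$ the social selection gradient. The covariance $C_{ij}'$ is the
quantity that creates the *opportunity* for social selection: when it is
zero, neighbors' traits exert no net selection regardless of how strong
$\beta_S$ is.

Here the trait is sex, coded hermaphrodite = 1 / female = 0 in exactly one
place (`sex_code()`), so that $C_{ij}' > 0$ always reads "plants tend to be
surrounded by their own sex". The social partners of a plant are the other
plants within a radius $r$, and everything in the package is computed across
a nested grid of radii (default 0.5--6.0 m in 0.5 m steps,
`radius_grid()`), because the scale over which pollinators move -- and hence
the scale over which sex ratio matters -- is unknown and likely small.

## Pipeline and conventions

**Mapping.** Field surveys record three GPS-referenced stations and, for
each plant, a triplet of distances measured with a sonic range finder.
`project_stations()` places the stations on a local equirectangular tangent
plane (sub-centimeter projection error over a ~100 m site, far below the
~1 m station accuracy, so nothing geodesic is warranted).
`trilaterate()` solves the circle-intersection system linearized by
subtracting the first circle's equation from the other two -- a unique
solution whenever the stations are not collinear -- followed by one
Gauss--Newton step on the three range residuals; at centimeter-level noise
further iterations change nothing. Each plant carries its RMS range misfit,
and `trilaterate_all()` flags (never drops) records whose misfit exceeds a
threshold defaulting to 1 m, the stated station accuracy. Because three
ranges constrain two coordinates with a single effective residual degree of
freedom, even badly inconsistent triplets can fit with sub-meter RMS; the
flag threshold is configurable for stricter screening.

**Neighborhoods.** A neighbor is any *other* plant at distance $\le r$
(closed ball; ties are measure-zero in real coordinates). Excluding the
focal plant is the standard convention in social selection analysis, and it
has statistical consequences discussed below. A plant with no neighbor at a
radius has an *undefined* local frequency (`NA`) -- the only convention that
keeps frequencies inside $[0,1]$ -- and is excluded from means, variances
and covariances at that radius; `n_defined` makes the exclusions visible.
The mean neighbor count averages over all plants, isolated ones included.
When a map holds several populations, plants never neighbor across
populations, and summary tables pool populations by default (per-population
tables are one `filter()` away).

**Scale statistics.** `scale_summary()` gives the per-radius mean and
sample variance ($n-1$ divisor throughout) of the local frequency.
`brown_forsythe()` tests heterogeneity of those variances across radii by
one-way ANOVA on absolute deviations from group medians.
`sex_by_scale_glm()` fits a logit-link binomial GLM of neighborhood
composition (hermaphrodite neighbors out of total, per plant x radius) on
sex, scale (categorical -- with 12 radii the scale blocks carry 11 df), and
their interaction, with sum-to-zero contrasts and type-III Wald chi-square
blocks. Both of these inherit a caveat: each plant contributes one value
per radius and nested neighborhoods overlap heavily, so the nominal
reference distributions are anti-conservative. A per-plant random intercept
would adjust those chi-squares but none of the covariance or selection
quantities downstream, so the package deliberately stops at the
fixed-effects fit and says so. `cross_scale_correlations()` gives the
radius-by-radius Pearson correlation matrix of local frequencies
(pairwise-complete plants, t-transform p-values, Holm adjustment across the
upper triangle).

**Two standardizations of $C_{ij}'$.** "Variance-standardized covariance"
admits two readings, and both are computed side by side:
$C_{\mathrm{std,cor}} = C_{raw}/\sqrt{P_{ii}P_{jj}}$ (a correlation) and
$C_{\mathrm{std,pii}} = C_{raw}/P_{ii}$ (focal-variance scaling). They are
not interchangeable diagnostics. At small radii the local frequency is an
average of one to three neighbors, so $P_{jj}$ is dominated by binomial
sampling noise; dividing by $\sqrt{P_{jj}}$ mechanically *attenuates* the
correlation exactly where neighborhoods are smallest, and the correlation
curve can rise over the first couple of meters even when the underlying
association is strongest there. The $P_{ii}$ convention is proportional to
the raw covariance and shows the decay undistorted; it is what the
package's scale-decay diagnostics use, while the correlation convention is
the default for reporting effect sizes on a bounded scale.

**Exclusion bias and the permutation null.** Because the focal plant is
excluded from its own neighborhood but enters the grand means, the plug-in
sample covariance between sex and local frequency is *not* centered on zero
under random labels: in the fully connected limit $f_i = (S - z_i)/(n-1)$
is a decreasing function of $z_i$ within every realization, and in general
$\mathrm{E}[C_{raw}] \approx -p(1-p)/n$ at every radius (about $-7\times
10^{-4}$ for $n \approx 320$ -- simulation reproduces this to within
Monte-Carlo error). The raw bias is tiny and radius-independent, but the
standardized versions divide by quantities that shrink with radius, so at
radii where a neighborhood spans a large fraction of the population the
*standardized* null mean is visibly negative. This is a property of the
estimator, not of the code; it is why significance claims about $C_{ij}'$
in this package rest on `permutation_null()`, which shuffles sex labels
over fixed coordinates and recomputes everything -- the null distribution
carries the same exclusion bias as the observed statistic, so the test's
size is calibrated (empirically exact in the suite). The full label
shuffle is a plain exchangeability null; it does not model spatially
restricted alternatives (no toroidal shifts or restricted randomizations).

**Selection arithmetic.** `natural_selection_differential()` computes the
variance-standardized covariance between sex and relative fecundity
$W/\bar W$: with a twofold female advantage ($W_F = 2, W_H = 1$) and the
pooled frequency of the two mapped populations it is $\approx -0.35$, the
inherent female seed-production advantage. `critical_social_gradient()`
inverts the model for the $\beta_S^*$ at which social selection exactly
cancels that differential, per radius via `selection_thresholds()`;
$\beta_S^*$ is exactly inversely proportional to $C_{ij}'$, so a radius
with a tenth of the covariance needs a tenfold stronger social gradient.
$\beta_S$ itself is a scenario parameter -- no fitness data enter the
pipeline -- so outputs are threshold curves, not fitted gradients.

## The synthetic generator

`generate_population()` is a Thomas cluster process (Poisson number of
uniform parents; Poisson offspring per parent displaced by an isotropic
Gaussian; offspring falling outside the window are discarded -- clamping
would pile plants on the boundary) with Beta-Bernoulli sex labels: each
cluster draws its hermaphrodite probability from
$\mathrm{Beta}(\kappa p, \kappa(1-p))$ and its plants are Bernoulli in it.
This is the minimal generator producing both patchy locations and
own-sex-biased neighborhoods whose covariance decays with radius; it does
not simulate the cytonuclear inheritance, environmental sex modification,
or pollinator movement that shape real populations, so passing tests
demonstrate statistical behavior of the estimators, not biology.

Defaults were calibrated once to the density regime of the two mapped field
populations rather than to a round window size: a 16 x 16 m window,
parent intensity 0.05 m$^{-2}$, 26 expected plants per parent, 1 m
dispersal, $p = 0.62$, $\kappa = 2$. That yields $n \approx 320$ plants,
about 2.4 neighbors within 0.5 m and ~110 within 6 m, and a local-frequency
variance falling from ~0.19 to ~0.008 across the grid -- the same order as
the field values (2.0 and 133 neighbors; 0.174 to 0.005). A sparser 30 x
30 m layout with the same $n$ was rejected because it puts the population
an order of magnitude below the field densities and loses the strong
small-scale structure that makes the scale analysis interesting.

One structural caveat, stated openly: within a cluster the mark correlation
is distance-*independent* (all plants share one Beta draw), so below the
dispersal scale the expected $C_{\mathrm{std}}$ curve is flat -- the
0.5 m and 1.0 m values are statistically indistinguishable -- and the decay
sets in from about the dispersal scale onward. Real populations, where
relatedness decays continuously with distance, can keep gaining covariance
all the way down. Decay diagnostics in the test suite therefore assert
strict decrease from 1.0 m on, and that the 0.5 m value exceeds everything
from 1.5 m on.

`generate_survey()` inverts the geometry module (true ranges plus Gaussian
noise) so the mapping pipeline can be exercised end to end;
`replicate_profiles()` runs replicate populations on a deterministic seed
schedule (replicate $i$ reseeds at `seed + i`, so a 10-replicate run is the
prefix of a 20-replicate run) and returns Monte-Carlo means and standard
errors of the scale curves.

## Numerical choices

- Degenerate geometry: stations are rejected when the triangle area falls
  below $10^{-9}\times\mathrm{span}^2$; a 2x2 system condition number above
  $10^8$ warns and flags the record.
- GLM fitting is `stats::glm` IRLS; non-convergence is an error carrying
  the iteration count and deviance, extreme coefficients (|log-odds| > 15)
  flag possible separation.
- Radii with fewer than two defined plants report `NA` statistics rather
  than erroring; all-one-sex subsets give undefined (not zero) covariance.
- Permutation p-values use the add-one rule
  $(1 + \#\{|C^\pi| \ge |C^{obs}|\})/(B+1)$, two-sided, $B \ge 99$; with
  several populations, labels shuffle within population.
- Undefined values serialize as empty CSV fields; doubles are written at 17
  significant digits so files round-trip exactly.

Simulation-based checks in the test suite use 40--200 replicate populations
of ~320 plants (500 for permutation-size calibration with $B = 199$) --
sizes at which every Monte-Carlo standard error quoted above is a few
thousandths while the whole suite runs in minutes.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 42)
pop <- generate_population(cfg)
prof <- neighborhood_profiles(pop)

scale_summary(prof)                      # Table-1-style mean/variance curves
brown_forsythe(prof)                     # heterogeneity of variances
covariance_profile(prof)                 # C_ij', P_jj, both standardizations
permutation_null(pop, radius = 0.5, n_perm = 999, seed = 1)

s_n <- natural_selection_differential(mean(sex_code(pop$sex)))
selection_thresholds(covariance_profile(prof), s_n, convention = "pii")
```

## Limitations

- The sex-by-scale regression is a fixed-effects approximation; its
  chi-squares are anti-conservative under the repeated-measures overlap and
  should be read as descriptive.
- No edge-corrected (Ripley-style) estimators: neighborhoods are truncated
  at the window edge exactly as a field survey truncates them.
- The critical-gradient curves condition on an assumed fecundity scheme
  (default twofold female advantage); they are thresholds, not estimates of
  realized social selection.
- The generator's clusters have sharp, distance-free internal sex
  structure; quantitative agreement with any particular field population is
  limited to the coarse density and variance regimes described above.
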