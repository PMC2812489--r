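# landrec

Landscape complexity and the long-term dynamics of animal populations.

`landrec` is a simulation-and-estimation toolkit for a question at the
junction of landscape ecology and population dynamics: how do patch
shapes (corridors), patch arrangement (configuration) and relative patch
cover (composition) affect a population's equilibrium size and its
ability to recover from disturbance? It is written for quantitative
ecologists and population modellers who want a reproducible, desk-scale
version of that experiment: a synthetic agricultural patch mosaic is
progressively simplified by three transforms, spatially explicit
individual-based models (IBMs) of four contrasting life histories are run
in each landscape variant under a periodic population-removal protocol,
and every run is summarized by fitting logistic recovery curves to yearly
log abundance.

## The model at the core

Yearly post-disturbance abundance is modelled on the log scale as

    ln N(t) = ln(K) / (1 + exp((m - t) / phi))

where `t` is years since the perturbation, `K` the equilibrium population
size, `m` the inflection time (abundance sqrt(K) there), and `phi` the
shape parameter: the log-scale deviation from equilibrium decays by a
factor e every `phi` years, so `phi` is the return time (reciprocal of
the return rate). Weather years `y` (a 10-year cycle of fecundity
multipliers) enter as random asymptotes, `ln K_y = ln K + b_y`,
`b_y ~ N(0, sigma_b^2)`. `fit_recovery()` estimates the model in two
stages (pooled Levenberg–Marquardt least squares, then empirical-Bayes
weather-year offsets) and attaches parametric-bootstrap 95% confidence
intervals; a 4-parameter variant with a lower asymptote serves
populations whose growth rate first accelerates after disturbance.

The landscape side provides `generate_landscape()` (raster patch mosaics
with immovable barrier elements and type-stratified, quarter-decade-
quantized patch sizes), the three transforms `homogenize_shapes()` (B:
corridors removed), `randomize_arrangement()` (C: configuration
randomized within size classes) and `randomize_sizes()` (D: composition
randomized), and ESRI-ASCII/CSV I/O for supplying real maps. The
population side provides `make_archetype()` ("beetle", "vole", "skylark",
"spider"), `step_year()`, and the protocol functions `make_schedule()`,
`run_experiment()`, `run_design()` and `run_pipeline()`.

## A worked example

Generate a small mosaic, disturb a beetle population by 95% every 17
years for 181 years, and estimate `K` and `phi` from the ten recovery
segments:

```r
library(landrec)

L <- generate_landscape(120, 250, seed = 11,
  barrier_layout = make_barrier_layout(120, road_spacing = 40, river = TRUE,
                                       n_buildings = 6, seed = 11))
L
#> landscape: 120 x 120 cells, cell size 50 m
#>   patches: 315  ( 65 barrier )
#>   cover: rotational_field 0.42, grassland 0.19, forest 0.12, field_boundary 0.10, ...

tr  <- run_experiment(L, make_archetype("beetle"),
                      make_schedule(removal_fraction = 0.95), seed = 99)
fit <- fit_recovery(segment_trajectory(tr), form = 3, n_boot = 200, seed = 1)
fit
#> 3-parameter logistic recovery fit
#>   K = 273.2, m = -0.0798, phi = 2.22 years
#>   95% CI: K [245.5, 309.5], phi [1.82, 2.66]
#>   sigma_b = 0.123, sigma_e = 0.376, n = 170

tr0 <- run_experiment(L, make_archetype("beetle"),
                      make_schedule(removal_fraction = 0), seed = 99)
fit_unperturbed(tr0)
#> equilibrium (intercept-only) fit: K = 703.6, sigma_e = 0.0588, n = 170
```

Reading the output: under repeated 95% removals the beetle recovers with
a return time of about 2.2 years (95% CI 1.8–2.7), toward an equilibrium
of roughly 270 individuals — well below the undisturbed equilibrium of
about 700 on the same landscape, because on this small mosaic recovery
between disturbances is incomplete in poor weather years. `sigma_b` is
the among-weather-year standard deviation of the log asymptote and
`sigma_e` the residual log-scale noise; `n` is the number of analyzed
yearly censuses. An early inflection (`m` near 0) simply places most of
the S-curve's rise in the first years after removal.

For the full factorial (species x removal intensity x landscape variant)
use `run_pipeline(pipeline_config(...))`, which returns a results table
of `K` and `phi` per cell plus per-species K–phi correlations and
consecutive-variant comparisons.

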