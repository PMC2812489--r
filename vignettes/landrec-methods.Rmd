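---
title: "Methods: landscape complexity and population recovery in landrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape complexity and population recovery in landrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the package addresses

How does the spatial structure of a landscape — the shapes of its habitat
patches, their arrangement, and the relative cover of patch types — shape
the long-term dynamics of the animal populations living in it? `landrec`
studies this with a simulation experiment: a synthetic agricultural patch
mosaic is progressively simplified by three transforms that strip out
corridors, configuration and composition in turn; desk-scale individual-based
models of four contrasting life histories are run in each variant under a
periodic population-removal protocol; and each run is summarized by two
classical quantities, the **equilibrium population size** $K$ and the
**return time** $\varphi$, estimated from logistic recovery curves fitted to
yearly log abundance.

The recovery model is

$$\ln N(t) \;=\; \frac{\ln K}{1 + e^{(m - t)/\varphi}},$$

where $t$ is years since a perturbation, $m$ the inflection time (log
abundance there is $\ln(K)/2$, i.e. abundance $\sqrt K$), and $\varphi$ the
shape parameter. On the log scale the deviation from the asymptote decays by
a factor $e$ every $\varphi$ years, so $\varphi$ is the e-folding return
time — the reciprocal of the return rate, also read as the (inverse)
strength of density dependence. Small $\varphi$ means fast return to
equilibrium. Because yearly weather modulates fecundity, the asymptote is
allowed to vary among weather years $y$ as $\ln K_y = \ln K + b_y$ with
$b_y \sim N(0, \sigma_b^2)$ — a random-asymptote (nonlinear mixed) model.

# The synthetic landscape generator

`generate_landscape()` is the data-generating stand-in for a real mapped
agricultural mosaic. It emulates the features of such maps that the four
archetypes' mechanisms actually touch:

* a raster of contiguous, typed patches completely tiling the non-barrier
  area, with a reduced controlled vocabulary of six habitat roles
  (rotational field, grassland, forest, field boundary, hedgerow, roadside
  verge) instead of a full habitat classification — the archetypes only
  distinguish these roles;
* immovable barrier elements (roads, a river, buildings, lakes, optionally
  railways) stamped before patch growth and never altered afterwards;
* a right-skewed, type-stratified patch-size distribution spanning more
  than two orders of magnitude: fields are drawn from the largest size
  range, linear elements from the smallest;
* linear elements grown with an axis-aligned elongation preference, so
  field boundaries and hedgerows form long, thin, corridor-like features
  threading between the compact blocks, as they do along real field edges.

Two generator choices deserve explanation.

**Quarter-decade area quantization.** Patch areas are binned throughout the
package into quarter-decade size classes,
$\mathrm{class} = \lfloor 4\log_{10}(\text{area in } m^2)\rfloor$. The
arrangement-randomization transform interchanges patch types *within* these
classes, so any within-class spread of areas leaks into per-type cover when
types are permuted. The generator therefore snaps target areas onto the
ladder of class-centre areas ($\mathrm{round}(10^{(j+0.5)/4})$ cells),
adjusting individual patches up or down one rung so the ladder sums exactly
to the available area. Patches in the same class are then interchangeable
by construction and per-type cover is conserved by the within-class
permutation to well under the package's 5 % tolerance. The spread and skew
of the size distribution are unaffected; only the within-class jitter is
removed.

**Growth and the deadlock rule.** The non-barrier area is tiled by
stochastic region growing: each patch starts at a seed cell, and at every
step one still-growing patch is selected with probability proportional to
the fraction of its target area it has left to grow (so nearly-complete
patches grow slowly) and claims one unclaimed cell 4-adjacent to its
current extent. Compact blobs cannot tile a plane, so growth alone leaves
junction gaps and occasionally walls a patch off before it reaches its
target. The deadlock rule has three stages: (i) a starved patch is frozen;
(ii) leftover unclaimed cells are assigned to the adjacent patch with the
largest remaining deficit (ties to the lowest identifier), keeping the
tiling total; (iii) an area-balancing diffusion then lets surplus patches
donate boundary cells to adjacent patches — directly into deficit, down a
surplus gradient, or laterally toward the nearest deficit patch in the
patch-adjacency graph — with every donation restricted to cells whose
removal keeps the donor 4-connected (a simple-point test). In practice this
drives per-patch areas to their targets exactly or within a few cells; the
packaged tests assert at least 95 % of patches exactly conserved and a
summed absolute deficit below 2 % for the shape-homogenization transform.

What the generator does **not** emulate: real patch geometry (no soil or
land-use template constrains where types occur), crop rotation and
within-year farming dynamics, type-specific adjacency preferences beyond
elongation, and any georeferencing. Passing tests therefore show that the
*mechanistic contrasts* (corridor loss, fragmentation, composition change)
behave correctly, not that any absolute $K$ or $\varphi$ transfers to a
real landscape. Real maps can be supplied instead of the generator through
`read_landscape()` (an ESRI ASCII grid of patch identifiers plus a CSV
attribute table).

# The three complexity-reduction transforms

* **B — `homogenize_shapes()`**: every habitat patch is regrown as a
  compact blob from its original centroid (snapped to the nearest member
  cell for concave patches), keeping identifier, type and area. This
  removes elongation — i.e. potential dispersal corridors — while leaving
  locations and sizes alone.
* **C — `randomize_arrangement()`**: type labels are permuted uniformly at
  random among non-barrier patches within each quarter-decade size class.
  Geometry is untouched; per-type patch counts are conserved exactly and
  per-type cover within a configurable 5 % tolerance (a warning is raised
  beyond it). Classes holding a single patch keep their type. Whether the
  interchange should pair strictly equal-sized patches or size-class peers
  was an open design point; the class-based reading was adopted because
  the class ladder is the package's sizing unit throughout, and strict
  equal-size pairing would leave every unique-sized patch fixed.
* **D — `randomize_sizes()`**: type labels are permuted over all
  non-barrier patches regardless of size, so the expected cover of a type
  becomes its patch-count frequency times the non-barrier area —
  composition change. Since linear elements are numerous and fields few,
  this typically shrinks total field cover and inflates boundary cover.

Barrier cells are bit-identical across A–D. `make_variants()` chains
B–C–D with independent stage-named sub-seeds; `replicate_landscapes()`
applies the chain repeatedly for replicate-landscape designs.

# The population engine

`step_year()` advances a population through one annual cycle with a fixed
phase order — **breed, disperse, overwinter** — and `census()` counts
individuals at the year start (1 January, after the previous overwinter).
A yearly cycle is the minimal faithful unit here because only yearly
censuses enter the analysis; daily farming and weather dynamics are out of
scope.

* **Breeding.** Each adult on a cell of habitat type $h$ produces
  $\mathrm{Poisson}\!\left(r_{\max} f_h w_y \max(0,\, 1 - n/(\kappa_h A))\right)$
  offspring, where $n$ is the patch's current adult count and
  $\kappa_h A$ the patch's carrying capacity. Density dependence is
  patch-level and emergent: there is no global regulation. Note the
  consequence that regulation acts on patch totals, not on local crowding
  within a patch — a deliberate simplification that makes the equilibrium
  of a single closed patch analytically checkable (below).
* **Dispersal.** Every juvenile draws a uniform direction and a uniform
  distance on $[0, d_{\max}]$ and walks the straight cell-centre
  rasterized path. Ground-bound archetypes stop at the cell before the
  first barrier cell (corners do not block); fliers/ballooners cross
  barriers at no cost but settle on the last non-barrier cell of the path.
  The grid edge halts movement (a closed world). Each disperser dies in
  transit with its archetype's dispersal mortality.
* **Overwinter.** Each individual survives with the survival probability
  of its cell's type. Semelparous archetypes' adults die after breeding;
  iteroparous adults overwinter like juveniles. Complementation archetypes
  survive only if some cell within $d_w$ (4-neighbourhood dilation steps)
  holds a complementation habitat type.

**Weather years.** A cycle of exactly ten log-normal multipliers with unit
mean (σ = 0.15 by default) is fixed per label and applied to fecundity by
calendar year, label $= (y-1) \bmod 10 + 1$. The labels are the random
grouping variable of the recovery fit, and a single weather sequence is
shared across all cells of a factorial design so weather years are
comparable between runs.

**Archetypes.** `make_archetype()` packages four parameterizations whose
*ordinal* contrasts carry the science; the absolute values are this
package's own calibration, chosen once so that all four populations are
demographically viable at the desk scale and sit in the stable regime of
the discrete logistic (per-year multiplication factors of roughly 1.4–3;
factors above ~2.6 produce overshoot oscillations that can zero fecundity
in a single patch and are avoided):

| archetype | pace | dispersal | barrier response | special mechanism |
|---|---|---|---|---|
| beetle | fast ($r_{\max}=6$), semelparous | short (3 cells) | blocked | overwinter survival requires field boundary/hedgerow within $d_w = 2$ |
| vole | slower ($r_{\max}=4$), iteroparous | short (4) | blocked | grassland specialist, elevated matrix mortality |
| skylark | slow ($r_{\max}=2.2$), iteroparous | long (40) | crosses | no breeding within $d_t = 2$ of forest/hedgerow |
| spider | fast ($r_{\max}=8$), semelparous | long (50) | crosses | ballooning: dispersal mortality 0.5; rates nearly habitat-flat |

The beetle couples two habitat types (summer fields, overwintering
boundaries): landscape complementation. The spider's near-flat rates make
it deliberately insensitive to configuration, the control archetype.

**Oracle equivalence.** In a single closed patch the engine collapses to a
scalar stochastic-logistic process. The tests code that scalar process
independently (same Poisson/binomial scheme, no space) and require the
spatial engine to match its yearly means within two Monte-Carlo standard
errors over 200 replicates, and the long-run mean to sit within 10 % of
the deterministic fixed point $\kappa A (1 - 1/(r_{\max} f s))$ of the
matched semelparous map at $\kappa A \ge 1000$.

# The perturbation–recovery protocol

The default `make_schedule()` is a 181-year run: 11 burn-in years, then a
removal of 80 % or 95 % of all individuals every 17th year. Removal takes
exactly $\mathrm{round}((1-\text{fraction})N)$ survivors uniformly without
replacement — an exact count, so removal intensity is not itself a noise
source — and is applied immediately after the 1-January census, so a
perturbation year's recorded $N$ is pre-removal.

One arithmetic point was genuinely underdetermined: with 181 total years,
11 burn-in years and a 17-year interval, the analyzed window (years
12–181, 170 records) can hold exactly ten complete 17-year recovery
segments only if the first removal happens at the burn-in boundary.
`landrec` therefore applies removals after the censuses of years
$11 + 17(k-1)$, $k = 1\ldots10$, making year 12 the first $t = 1$ census.
The alternative (first removal after the year-12 census) would push the
tenth segment past the end of the run. This is a declared design choice,
not an inference.

Zero-abundance years keep their records with an undefined log marker; they
are excluded from fitting but counted, never silently dropped. Extinction
is a valid outcome: the trajectory completes with zeros and is flagged.

`run_design()` runs the full factorial (by default 4 archetypes × 3
intensities × 4 variants = 48 cells) with per-cell sub-seeds drawn without
replacement from the master seed; a failing cell is recorded without
disturbing the others.

# Estimating K and phi

`fit_recovery()` pools all segments of a run and fits log abundance
against time since perturbation. Estimation is two-stage:

1. **Pooled nonlinear least squares** (Levenberg–Marquardt) for the fixed
   parameters. Starting values: $\ln K_0 = \max \ln N$; $m_0$ = first $t$
   with $\ln N \ge \ln K_0 / 2$; $\varphi_0$ = segment length / 8; bounds
   $\varphi \in [0.05,\, 10 \times \text{segment length}]$. A fit whose
   $\varphi$ lands on a bound, or whose optimizer fails, or whose response
   carries no growth signal (zero variance), returns
   `converged = FALSE` with a diagnostic and no intervals — never an
   exception.
2. **Weather-year asymptote deviations** $b_y$ from label means of
   late-window residuals ($t \ge \hat m$), with empirical-Bayes shrinkage
   $\lambda_y = \sigma_b^2/(\sigma_b^2 + \sigma_e^2/n_y)$ and variance
   components by method of moments (within-label pooled variance for
   $\sigma_e^2$; between-label variance of means, bias-corrected, for
   $\sigma_b^2$, clipped at zero).

This two-stage scheme reproduces the quantities of interest — $K$,
$\varphi$, and the among-year variation — with a transparent, testable
algorithm rather than a full Lindstrom–Bates linearization; the contract
(estimates, intervals, convergence flag) is what is pinned, not the
algorithm. A packaged test cross-checks the estimates against an
independent `nlme` fit of the same random-asymptote model and requires
agreement within 5 %.

95 % confidence intervals for $K$ and $\varphi$ come from a parametric
bootstrap of the full two-level model (fresh $b_y^\*$ and residuals per
replicate, 200 replicates by default, percentile intervals). At the
default design — 10 segments × 17 years, 10 labels, $\sigma_e = 0.1$,
$\sigma_b = 0.2$ — the packaged calibration study requires median relative
errors of $\hat K$ and $\hat\varphi$ below 10 % and empirical interval
coverage of at least 85 % over 200 replicates.

The **4-parameter form** $A + (\ln K - A)/(1 + e^{(m-t)/\varphi})$ adds a
lower asymptote for populations whose growth rate initially increases
after disturbance; the skylark archetype uses it by default. With
`form = "auto"`, form 4 is chosen when a one-sided runs test finds
structured early-time ($t \le \hat m$) residuals in the form-3 fit. The
exact 4-parameter variant in use elsewhere is not standardized; the
lower-asymptote logistic is this package's declared choice.

Unperturbed runs get `fit_unperturbed()`: an intercept-only model on log
abundance whose intercept varies among weather years; $K$ is the
exponential of the mean intercept, and no return time is defined.
`segmentwise_K()` profiles a shared $(m, \varphi)$ while freeing one
asymptote per segment — for fixed $(m,\varphi)$ each segment's $\ln K_k$
has the closed form $\sum g\,\ln N / \sum g^2$ with
$g(t) = 1/(1+e^{(m-t)/\varphi})$ — enabling the repeated-perturbation
trend test (`recovery_decline_test()`, a weighted linear trend whose 95 %
CI entirely below zero flags incomplete recovery).

One numerical caveat: the tail e-folding property
$\big(\ln K - \widehat{\ln N}(t)\big)$ shrinking by $e$ per $\varphi$
years is exact only asymptotically; at $t = m + 10\varphi$ the ratio is
$e\,(1 + O(e^{-10}))$, about $3\times10^{-5}$ away from $e$. Tests assert
it at $10^{-4}$ there and at $10^{-6}$ ten e-foldings further out.

# Cross-cutting analysis

`correlate_K_phi()` computes the Pearson correlation between $K$ and
$\varphi$ for one species across converged *perturbed* landscape ×
intensity cells (unperturbed cells contribute $K$ only, never $\varphi$),
with a t-distribution p-value; degenerate inputs return an undefined
marker. No multiple-testing correction is applied, deliberately — raw
correlations are reported with their $n$. `compare_variants()` differences
$K$ and $\varphi$ between consecutive variants with intervals propagated
in quadrature from the fits' bootstrap intervals. `run_pipeline()` chains
generate → variants → simulate → fit → analyze under one seed and
optionally writes TSV/JSON artifacts.

# Problem sizes and study conditions

The desk scale is a 200 × 200-cell grid (cell size 50 m, so the grid
spans the same 10 × 10 km as a full-scale map at 1 m resolution) with 500
habitat patches, a road grid, a river, buildings and a lake. All study
conditions are the schedule defaults above. The packaged acceptance tests
run: transform conservation on a 50-patch landscape; cover conservation
and the composition law at the full desk scale (200 randomization seeds);
fitting exactness, a 100-replicate error study and a 200-replicate
coverage study at the 10 × 17 design; oracle equivalence at 200
replicates; and the directional mechanism checks — beetle $K$
non-increasing from A to C, beetle $K$ collapsing when overwintering
habitat is displaced beyond $d_w$, spider $K$ insensitive to arrangement —
seed-averaged over 10 replicate landscapes at the full desk scale. The
script `scripts/acceptance.R` reruns the complete 48-cell factorial from
one seed and writes every headline quantity it computes.

# Known limitations

* Patch-level density dependence ignores within-patch crowding, so a
  patch's capacity can be realized inside a narrow habitable fringe; the
  complementation mechanism consequently operates through patches losing
  *access* to overwintering habitat rather than through graded area loss.
* Absolute $K$ and $\varphi$ are properties of the synthetic landscape
  and the archetype calibration; only ordinal and directional contrasts
  are meaningful, and none of the absolute values are comparable to any
  real landscape.
* The annual cycle compresses all within-year mortality into two phases;
  there is no individual condition, territoriality, or farming calendar.
* The elongation model for linear elements is a growth preference, not a
  geometric template; corridors meander rather than following field
  edges.
* `fit_recovery()`'s two-stage estimator attenuates $b_y$ slightly at
  early times (offsets enter through the logistic, not additively); the
  bootstrap inherits the same structure, so interval calibration is
  verified empirically rather than assumed.
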