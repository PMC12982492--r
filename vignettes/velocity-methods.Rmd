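---
title: "Climate-velocity estimators and species range-shift tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-velocity estimators and species range-shift tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velomatch)
```

## The problem

Species respond to a warming climate by shifting their distribution ranges.
Whether a population keeps pace depends on how fast suitable conditions move,
which requires turning a scalar climate field $\psi(x, y, t)$ (here:
temperature) into a horizontal velocity field. That conversion is
underdetermined — a moving isotherm tells you how fast conditions change
*across* itself, not in which direction material points travel — so every
climate-velocity index embodies a directional assumption. This package
implements and compares two:

**Gradient method.** The classical index defines the speed of isotherm
displacement as
$$ v \;=\; \frac{\partial \psi / \partial t}{\lVert \nabla \psi \rVert}, $$
directed down-gradient (warming on a poleward-cooling field gives a poleward
vector). In vector form, as implemented in `gradient_velocity()`:
$$ \mathbf{v} \;=\; \frac{\partial \psi}{\partial t}\,
   \frac{-\nabla \psi}{\lVert \nabla \psi \rVert^{2}}. $$
The down-gradient assumption is exact when isotherms are straight, parallel,
and shift uniformly; it degrades when topography or coastlines curve them.
The index also blows up where $\lVert\nabla\psi\rVert \to 0$: a flat
temperature plateau implies absurdly fast velocities. Nodes with gradient
magnitude below `min_grad` (default $10^{-4}$ °C/km; the zeroing rule is
standard, the threshold is a package choice since no canonical value exists)
are therefore masked invalid and set to exactly zero, which keeps the field
finite everywhere at the cost of discarding those locations.

**Monte-Carlo iterative convergence (MATCH-style).** `match_velocity()`
treats the problem as image registration: find a per-node displacement field
$D$ (km) that warps the initial decadal-mean field onto the final one while
staying as regular as possible. Starting from $D = 0$, one node's
displacement at a time is perturbed by an isotropic Gaussian step and the
move is kept iff the objective strictly decreases:
$$ E(D) \;=\; \underbrace{\frac{1}{\mathrm{MSD}_0}\sum_{\text{nodes } i}
   \bigl(\psi_0(x_i - D_i) - \psi_1(x_i)\bigr)^2}_{\text{misfit}}
   \;+\; \lambda \underbrace{\sum_{\langle i,j \rangle}
   \frac{\lVert D_i - D_j \rVert^2}{L_{ij}^2}}_{\text{shear}} $$
with 4-neighbour pairs $\langle i,j\rangle$, local cell size $L_{ij}$, and
$\mathrm{MSD}_0$ the mean squared field difference at $D=0$. The final
$D/\Delta t$ is the velocity. Instead of assuming a direction, the shear
penalty selects, among all deformations that explain the observed change,
the most regular one.

## Numerical choices

* **Normalisation of the objective.** Misfit is measured in units of the
  initial mismatch and shear in squared cell units, so both terms are
  dimensionless and the default $\lambda = 1$ weights them comparably on any
  grid and any field amplitude. With raw units (°C² vs km²) no single
  $\lambda$ would work across scenarios: a 20 km single-node move would cost
  ~10³ km² of shear against a fraction of a °C² of misfit and the greedy
  loop could never leave $D = 0$.
* **Backward warp.** The misfit interpolates $\psi_0$ at $x - D$ (bilinear,
  degree space, clamped to the nearest edge value outside the grid) rather
  than scattering displaced vertices forward. $D$ remains the forward
  displacement of the pattern — on a parallel-isotherm field warming at rate
  $b$ over gradient $a$, the minimiser is the uniform poleward shift
  $D = b\,\Delta t/a$, which the test suite asserts.
* **Greedy acceptance.** Moves are kept only on strict improvement; no
  annealing temperature. The accepted-move objective sequence is therefore
  strictly decreasing, a property tests check directly. On fields linear in
  the displacement (all scenarios shipped here) $E$ is a convex quadratic,
  so greedy coordinate descent converges to the global minimum; on rugged
  real fields, restarts with different seeds are cheap (the hot loop is
  compiled) and the parallel-scenario tests confirm seed-independence of the
  solution within tolerance.
* **Proposals and stopping.** One uniformly random node per iteration,
  Gaussian step with sd = `proposal_scale` × local cell size (default 0.25
  cells); stop at `budget` proposals (default 200 × nodes) or after
  `stall_limit` consecutive rejections (default 20 × nodes). The defaults
  register the shipped scenarios to under 1% residual misfit in well under a
  second on a 30 × 30 grid; they are exposed in `match_config()` because
  harder fields will need larger budgets. A smaller `proposal_scale`
  polishes the converged field further (less node-level jitter) at the cost
  of slower large-displacement moves.
* **Geodesy.** One constant serves all modules: $K = 111.195$ km per degree
  (sphere of radius 6371 km), zonal distances scaled by $\cos(\mathrm{lat})$.
  Shift components use this equirectangular local metric rather than exact
  geodesics — at decadal shift scales (tens of km) the difference is far
  below observation noise, and consistency with the gridded fields' metric
  matters more. Spherical rather than ellipsoidal geodesy costs well under
  0.5% at continental scale.
* **Geodesic centroids.** `geodesic_centroid()` computes the true weighted
  Fréchet mean on the sphere (the point minimising weighted squared
  great-circle distance), by tangent-space iteration from the normalised
  vector-mean start. The plain renormalised vector mean was rejected: for
  asymmetrically weighted clouds spanning tens of degrees it deviates from
  the geodesic mean by ~0.1°, which is material at the precision the tests
  demand. Adding the centroid itself as an extra point leaves the solution
  fixed, and the result is permutation-invariant; both are asserted.
* **Nearest-node velocity lookup.** `velocity_at()` deliberately does not
  interpolate: interpolation would blend masked (zeroed) nodes into their
  neighbours and silently re-introduce the blow-up values the mask removed.
* **Δt convention.** The interval between two decadal means is the offset of
  their window midpoints, so consecutive half-open decades give exactly
  10 yr.

## Range shifts from observation records

Records follow the schema `species_id, site_id, year, lat, lon, count,
presence`. Two survey modes are supported, with the inclusion criteria of
long-running North-American programmes:

* **Birds (count data):** a species is kept only with ≥ 5 reports in every
  year of both decades under comparison; an observation spot is kept for a
  species only if it reports that species every year with ≥ 2 observations.
  Failing spots are dropped first; by default the ≥ 5 rule is then
  re-checked on the surviving records (`species_counts = "post_site"`), with
  the pre-filter reading available because the criteria can be read either
  way.
* **Marine (presence data):** automated trawl surveys define no spots; the
  spot rule is replaced by ≥ 3 observations per year.

Per species, yearly centroids (count-weighted for birds) are geodesically
averaged, then the yearly centroids are averaged unweighted into a decadal
centroid; the offset between two decadal centroids over the midpoint
interval gives the shift velocity, decomposed into longitudinal and
latitudinal km/yr. Elevational (or depth) velocity comes from sampling a
signed-elevation DEM (bathymetry negative) at the two centroids — one axis
convention covers mountain birds and deepening fish alike. Headings are
degrees clockwise from north and undefined at zero magnitude; undefined
headings are excluded from circular summaries, never imputed as 0.

## The comparison layer

`build_comparison()` pairs each species × decade-pair track with the climate
velocity at its *initial* centroid from each estimator, plus a climate
elevational velocity obtained by displacing that centroid along the climate
vector over the full period offset and differencing the DEM (a per-year
displacement variant is exposed as `elev_displacement = "per_year"`). Then:

* `component_fit()` — per-component OLS with outlier removal at 1000 km/yr
  (horizontal components; the elevational unit is m/yr, so its threshold is
  a separate optional argument — a documented divergence risk), slope ± SE,
  Pearson r, two-sided p.
* `mixed_fit()` — aggregating decade pairs repeats species, so a linear
  mixed model with a species random intercept (ML, z = estimate/SE) is used
  for aggregated analyses.
* `multilinear_fit()` — each species component on all three climate
  components jointly, to check crossed-axis influence; collinear designs are
  flagged.
* `heading_summary()` — circular mean/sd of heading differences via the
  resultant vector.
* Region splits default to the −100° meridian (`split_lon`), separating the
  climatically contrasted western and more homogeneous eastern halves of a
  North-American domain.

No multiple-testing correction is applied across components or decade
pairs; p-values are reported per fit and should be read accordingly.

## What the synthetic generator emulates — and what it does not

`field_scenario()` produces yearly temperature grids
$$ \psi = \psi_0 - a\,d(\mathrm{lat})
   + c \sin\!\bigl(k\,(\mathrm{lon}-\mathrm{lon}_0)\bigr)
   + b\,\bigl(1 + m \sin(k_b (\mathrm{lon}-\mathrm{lon}_0))\bigr)\,t $$
covering the geometries that matter for the estimator comparison: parallel
isotherms (`parallel`; both estimators must agree with the closed form
$v = b/a$), curved isotherms with longitudinally modulated warming
(`curved`; the true deformation — a purely meridional shift varying with
longitude — exists on-grid, so the registration can in principle reach zero
misfit while the down-gradient direction is wrong), and near-zero-gradient
plateaus (`flat_patch`; exercises the blow-up guard). Default magnitudes are
chosen at observed mid-latitude scales: $a = 0.01$ °C/km (~1 °C per degree
of latitude), $b = 0.02$ °C/yr (~0.2 °C per decade), 0.5° grids, 20-yr
series giving two decadal means.

`species_scenario()` advects each species' true centroid yearly at
`tracking` × the local velocity (nearest node) and scatters a fixed roster
of sites i.i.d. Gaussian (sd `noise_sd` km) around it; each site yields
`obs_per_site_year` records, with Poisson counts (clipped ≥ 1) in birds
mode. A `species_drift_sd` adds a per-species constant velocity offset —
the species-level heterogeneity the mixed model is meant to absorb.
Fractions of species and sites can be engineered to fail each inclusion
criterion, giving the filters known positive and negative cases; tests
assert exact agreement with a brute-force nested-loop oracle.

The generator deliberately does **not** mimic volunteer spatial bias,
coastline-constrained survey geometry, observer-density trends, or
interannual climate variability beyond the linear trend. Passing tests
therefore demonstrate correctness of the estimators, filters, geodesy and
statistics under clean assumptions — not robustness to the sampling
pathologies of real survey data.

## Fixture scale and test design

Tests run on 30 × 30 (0.5°) grids, 20-year series, and 50–120 synthetic
species — sizes chosen so the full suite exercises every stage, including
two Monte-Carlo registrations and mixed-model parameter recovery at
$s \in \{0, 0.5, 1\}$, in about a minute. Parameter-recovery assertions use
3-SE bands around the generating values; estimator-agreement assertions use
the 10% bands that the parallel-scenario closed form motivates. The
method-discrimination check uses a strongly curved fixture
(`curve_amp = 5` °C, `curve_k = 0.4` rad/deg) where the down-gradient
direction is badly wrong over part of the domain — the regime the
comparison is about — with species advected by each estimator's field in
turn and refitted against both.

## Known limitations

* The Monte-Carlo loop here honours the published verbal contract (local
  random deformations, accept on improvement, shear penalty, vertex
  displacement = velocity) but is an independent implementation; exact
  numerical agreement with other implementations is not claimed, and the
  proposal law and stopping rule are package choices.
* Whether the spatial gradient should be evaluated on the initial field, the
  final one, or their average is not settled usage; this package uses the
  initial field, consistently with sampling climate velocity at the initial
  centroid.
* Centroids compress a range to a point; leading/trailing edge dynamics are
  out of scope.
* The domain is a bounded regional box: no spherical wrap-around in the
  registration, and nodes at the boundary have fewer shear neighbours.
  Backward warps falling outside the grid clamp to the edge value, so a
  narrow boundary band of the MATCH field is biased low; interior-node
  assertions account for this.
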