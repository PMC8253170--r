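---
title: "Canopy light interception models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy light interception models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canlight)
```

## The problem

Crop growth models that use the light-use-efficiency approach compute daily
biomass gain as `LUE * IPAR`, where IPAR is the photosynthetically active
radiation intercepted by the canopy. Interception is almost universally
modelled with the Beer–Lambert big-leaf relation

$$\mathrm{FIPAR} = 1 - e^{-K \cdot \mathrm{GAI}},$$

where GAI is the green area index (one-sided lamina area plus half the
developed area of stems and ears, per unit ground area) and $K$ is an
extinction coefficient. Everything interesting hides in $K$: it depends on
the inclination of the foliage, the direction of the incoming light, and
the spatial aggregation (clumping) of the elements. Wheat crop models in
wide use disagree about $K$ by more than a factor of two (constants from
0.37 to 0.80), and this package exists to quantify what that disagreement
does to intercepted light, biomass and yield, and to provide the
physically based alternative.

## The model family

`extinction_model()` names eight families, mirroring the conventions of the
crop models that use them:

| name | direct-beam $K$ | diffuse-sky convention |
|------|------------------|------------------------|
| `Kcst` | constant (default 0.52, the ensemble median) | same constant |
| `Kcstds` | $1.5 - 0.768\,(d s^2)^{0.1}$ from plant density $d$ and row spacing $s$ | same value |
| `KcstHS` | 0.5, rising linearly to 0.6 between the Haun stage $\omega = 0.973\,\mathrm{FLN} - 0.777$ and the final leaf | same value |
| `Kavr` | $G(\beta,\bar\theta)/\sin\beta$ with all elements at the mean inclination $\bar\theta$ | three-class overcast-sky log-average |
| `Ksph` | $0.5/\sin\beta$ (spherical facet orientation) | constant 0.6 |
| `KsphC` | $C_{sph}\cdot 0.5/\sin\beta$, $C_{sph} = K^{dif}_{meas}/(0.8\sqrt{1-\sigma})$ | $K^{dif}_{meas}$ (default 0.6, giving $C_{sph}=0.75$) |
| `Kell` | $\sqrt{\chi^2+\cot^2\beta}\,/\,\Lambda(\chi)$, $\Lambda(\chi) = \chi + 1.774(\chi+1.182)^{-0.733}$ | hemispheric integral of the directional FIPAR |
| `KellC` | $C_{GAI}\cdot K_{ell}$ | hemispheric integral |

$\beta$ is the sun elevation and $\chi$ the eccentricity of the ellipsoidal
leaf-angle distribution ($\chi = 1$ spherical, $\chi > 1$ planophile,
$\chi < 1$ erectophile). The diffuse hemispheric integral is

$$\mathrm{FIPAR}_{dif} = 2\int_0^{\pi/2}\mathrm{FIPAR}_{dir}(\beta)
  \cos\beta\,\sin\beta\,d\beta,$$

evaluated with 32-node Gauss–Legendre quadrature (configurable through
`extinction_model(quad_order=)`). For a constant $K$ the integral collapses
analytically to the constant-K FIPAR, which the quadrature reproduces to
1e-10 — a useful exactness check.

### The ellipsoidal distribution and its empirical mean-angle relation

The inclination density is
$g(\theta) = 2\chi^3\sin\theta / [\Lambda(\chi)(\cos^2\theta +
\chi^2\sin^2\theta)^2]$, with $\Lambda$ an approximation to the normalized
ellipse area. Because $\Lambda$ is approximate, the density integrates to 1
only to within about 0.5%, and that tolerance is inherited by everything
downstream.

The mean inclination is linked to $\chi$ by the empirical power law
$\chi = (\bar\theta/9.65)^{-0.6061} - 3$ **with $\bar\theta$ in radians** —
a unit convention that is easy to get wrong and is therefore stated in the
documentation of `chi_from_theta_mean()`. The relation is empirical: its
prediction differs from the numerical first moment of $g$ by up to
~2.1 degrees over $\chi \in [0.5, 3]$ (worst near $\chi = 0.5$, where the
first moment is 72.1 degrees but the relation maps 70 degrees to
$\chi = 0.50$). Tests that check sampling consistency therefore compare
against the first moment, and the package never treats the two as
interchangeable beyond that documented tolerance.

A related consequence: the relation stays positive over the whole open
domain $(0, \pi/2)$ — its root sits just past 90 degrees — so the
out-of-validity guard for non-positive $\chi$ is defensive only.

### The discrete 13-class formulation

`k_ell_discrete()` averages a per-class coefficient over 13 inclination
classes (midpoints 5, 15, ..., 75, 81, 83, 85, 87, 89 degrees). The classes
are unevenly spaced — 10-degree classes up to 80 degrees, 2-degree classes
above — so the class frequencies must be $g(\theta_i)$ *times the class
width*; without the widths the steep classes are overweighted five-fold and
the formulation disagrees with the closed form by ~27%. With the widths the
two agree to better than 0.8% across $\chi \in [0.5, 3]$ and
$\beta \in [15°, 75°]$, which the test suite locks in at a 1% bound. The
per-class transition angle $\arccos(-\tan\beta/\tan\theta_i)$ is clamped to
$[-1, 1]$ before the arccosine to absorb floating-point noise at
$\theta_i = \beta$.

## Solar geometry and diffuse/direct partitioning

`solar_position()` uses the standard declination / hour-angle formulas in
*solar time*: solar noon at hour 12, no equation-of-time or longitude
correction, because weather inputs in this domain are conventionally
declared in solar hours. Elevations are symmetric about noon to 1e-9
radians, which the tests assert.

The diffuse fraction of measured PAR is obtained from the hourly
clearness-index relations of Spitters et al. (1986): fully diffuse below a
clearness of 0.22, `1 - 6.4 (R - 0.22)^2` to 0.35, then `1.47 - 1.66 R`
down to a clear-sky floor `f0 = 0.847 - 1.61 sin(beta) + 1.04 sin^2(beta)`.
The source literature this package builds on cites the approach without
printing the equations, so the piecewise thresholds here are an
implementation choice, documented rather than asserted against any
publication. The strategy is swappable: `constant_diffuse_fraction()` or
any function with the same signature can be passed to `read_weather()`.

The standard overcast sky has radiance $L(\beta) \propto 1 + 2\sin\beta$
(the normalization cancels in all uses). Its three 30-degree class weights
computed analytically are (0.1786, 0.5140, 0.3074); the classic printed
triplet (0.178, 0.514, 0.308) agrees to within 6e-4 and both are accepted
by the tests at an absolute tolerance of 1e-3.

## The synthetic canopy generator and the ray-cast reference

`generate_canopy()` builds labelled triangle meshes emulating a drilled
cereal stand:

* plants on parallel rows, **uniformly (Poisson) placed along the row** —
  near-regular spacing would produce sub-Poisson overlap (directional
  clumping factors above 1 at mid elevations), an artifact no drilled
  stand shows;
* per-organ inclination distributions (ellipsoidal laminas, near-vertical
  stems with a 3-degree jitter to avoid a degenerate stand), uniform
  azimuth;
* leaf area concentrated within a dispersion radius of each plant axis
  (default 0.06 m, the lateral spread of foliage at the start of stem
  extension). Clumping is an *emergent* property: at default settings and
  0.175 m rows the hemispheric clumping factor comes out near 0.78,
  matching the regime observed in the field at that spacing, and it drops
  when the row spacing doubles;
* per-triangle area tuned so the realized GAI matches the target exactly;
  the default element area (2e-4 m^2) is small relative to the footprint
  so unclumped scenes approach the turbid-medium limit;
* `arrangement = "uniform"` places every triangle independently, producing
  a true Poisson canopy whose gap fractions obey
  $e^{-K(\beta)\,\mathrm{GAI}}$ in expectation — the package's core
  geometric oracle.

`gap_fraction()` is specified as ray casting from stratified-random ground
points with periodic wrap-around; it is implemented as the exactly
equivalent shadow projection of each triangle onto the ground torus with
2-D point-in-triangle tests, which avoids 3-D intersection code entirely
(opaque elements, binary hit). The reported standard error is binomial,
which slightly overstates the error of stratified sampling — conservative
in every test that uses it. Identical seeds reproduce scenes and gap
fractions bit for bit.

What the generator does **not** emulate: leaf curvature and twisting
(elements are flat), azimuthal anisotropy, vertical gradients of leaf
angle, and the hemispherical-camera geometry of image-based references
(no camera height concept). Passing tests show the model family's
behaviour against geometrically ideal canopies of known composition, not
against real digitized plants.

## Effective GAI, clumping, and a numerical trap

Directional gap fractions are inverted to an effective GAI with

$$\mathrm{GAI}_{eff} = 2\int_0^{\pi/2} -\ln(\mathrm{GF}(\beta))
  \cos\beta\,\sin\beta\,d\beta,$$

and the clumping factor is $C_{GAI} = \mathrm{GAI}_{eff}/\mathrm{GAI}_{mes}$.
`scene_effective_gai()` evaluates the integral over 10-degree elevation
rings (matching the ring processing of image-based canopy analysis), with
ring weights *normalized* so that a direction-independent gap fraction
inverts exactly to $-\ln(\mathrm{GF})$; a Gauss–Legendre alternative is
provided and agrees within 2% on smooth scenes. Totally occluded rings are
floored at a configurable `gf_min = 1e-4` with a warning.

`effective_gai_from_fipar()` inverts analytic or measured FIPAR profiles
with Gauss–Legendre quadrature (default order 32). A numerical trap lives
at the horizon: for a dense canopy the profile saturates — in double
precision `1 - exp(-K*GAI/sin(beta))` rounds to exactly 1 once the exponent
passes ~37 — and the inversion would return infinity. The function refuses
saturated nodes by default, with two escape hatches: a `cap` just below 1
(biases the retrieval low, hence not silent), or a lower quadrature order
(order 8 keeps all nodes above ~1.8 degrees, where a GAI-2 spherical
profile is still representable; the analytic identity
$\mathrm{GAI}_{eff} = \mathrm{GAI}$ then holds to 0.1%).

## Daily integration and the growth coupling

`fipar_daily()` weights instantaneous FIPAR
($f\,\mathrm{FIPAR}_{dif} + (1-f)\,\mathrm{FIPAR}_{dir}$) by incident PAR
over daylight steps; records with sun elevation below 1 degree or zero PAR
are treated as night (the integration bounds are sunrise to sunset, with
twilight excluded deliberately). Step widths come from the record spacing,
with trapezoid-style local widths for irregular series; halving the step
changes the daily value by under 0.2% for smooth weather.

`run_season()` is a deliberately minimal light-use-efficiency coupling:
thermal time (base 0 °C) drives a *prescribed* piecewise-linear GAI
trajectory and a mean inclination that is constant to the start of stem
extension, ramps linearly to flag-leaf ligulation, and is constant after;
the clumping factor is constant throughout; biomass accumulates as
`LUE_eff * IPAR` and yield is a fixed harvest index times final biomass.
There is **no feedback of biomass on GAI** — in a full crop model a light
deficit early in the season also slows canopy expansion, amplifying the
differences between light models. The relative differences the package
computes across models are therefore conservative lower bounds on what a
feedback-coupled model would show, and the qualitative ordering (which
model intercepts more, and where) is the meaningful output, not the
percentages.

The optional diffuse-light response
`LUE_eff = LUE (1 + slope (f_day - f_ref))` is a linear hook (default
slope 0, i.e. constant LUE) emulating the adjustment some constant-K crop
models apply on cloudy days. It is a configurable placeholder, not a
calibrated response curve.

Default growth parameters: LUE 3.0 g MJ⁻¹ (PAR basis, typical for
well-fertilized wheat), harvest index 0.45, phenology thresholds 600 /
900 / 2000 °C d for stem extension, flag leaf and maturity, GAI anchors
rising to 5 m² m⁻² at flag leaf. `synthetic_season_weather()` generates
hourly PAR as clear-sky extraterrestrial PAR scaled by a beta-distributed
daily clearness (mean 0.55, shape 8), with the diffuse fraction from the
partitioning model — it reproduces the latitudinal gradient of sun
elevation and day length, not real synoptic weather.

## The intercomparison harness and its statistics

`run_intercomparison()` scores every model against the ray-cast reference
of each scene, on a 10–85 degree elevation grid in 5-degree steps,
azimuth-averaged, using the scene's *own* summary (measured GAI, mean
inclination mapped to $\chi$, ray-cast clumping factor) as the canopy
state. The diffuse comparison inverts the same ring gap fractions.

Because the reference is Monte Carlo, rankings are only asserted when the
RMSE difference exceeds twice its standard error. That standard error is
computed by the delta method on the *paired* per-point squared-error
differences — the two models share each reference point, so pairing
removes the common reference noise; using the per-point reference SE
directly would overstate the uncertainty of a 32-point aggregate roughly
five-fold.

Problem sizes used by the shipped tests and acceptance checks, chosen to
keep every Monte-Carlo bound a factor of a few away from its tolerance:
scenes of 1.2 GAI over 0.7 × 0.7 m footprints (roughly 5 000 triangles at
the 1.5e-4 m² element area), 1e4–2e4 rays per cast, four azimuths per
elevation, two-scene ensembles for rankings, 1e6 draws for the brute-force
hemisphere average, 1e5 draws for distribution-mean checks, and 200–260
day seasons at five latitudes from 14° to 61°.

## Registry conventions

The packaged registry (`cgm_model_registry()`) transcribes the 26-model
ensemble table: extinction-coefficient type, constant value or range,
diffuse coefficient for the spherical family, which organs are counted,
biomass approach and time step. Models listed with a range enter the
ensemble median as their midpoint — a convention of this package, since
published ensemble medians do not state how ranges were collapsed; with it
the constant-K median evaluates to 0.52. The registry maximum is 0.80.

## Known limitations

* FIPAR is used as a stand-in for FAPAR (black elements, black soil); fine
  for PAR over most soils, untested for bright backgrounds.
* Clumping is direction-independent in all clumped models, while the
  synthetic scenes show a ±10% directional variation around the
  hemispheric value — the model error this induces is part of what the
  intercomparison measures.
* No multi-layer or sun/shade canopy: one big leaf.
* The growth coupling omits nitrogen, water, CO₂ and temperature stress,
  and grain-filling dynamics.
* The ellipsoidal density inherits the ~0.5% normalization error of the
  $\Lambda$ approximation; the spherical special case of the closed form
  is 0.4997, not 0.5, for the same reason.
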