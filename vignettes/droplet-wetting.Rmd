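---
title: "Methods: sessile-droplet evaporation and forced wetting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sessile-droplet evaporation and forced wetting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropwet)
```

This vignette is the package's account of the science it implements:
the models, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The measurement problem

A droplet of bacterial suspension deposited on glass evaporates; as
it loses water the suspended cells densify, settle and begin to
adhere. If the substrate is then rotated so that a growing
centrifugal force pulls tangentially on the droplet, the speed at
which the droplet first spreads, and the speed at which its rear
edge finally lets go (sliding), measure how strongly the droplet —
and the cells anchoring its contact line — resist removal. The
package turns side-view image series of such experiments into
numbers: contact angles, lengths, heights, volumes, evaporation
rates, onset speeds, Bond numbers and Furmidge retention factors.

## Drop shape: the axisymmetric Young–Laplace equation

An axisymmetric sessile drop at rest satisfies, in arc-length form
(Bashforth–Adams),

$$\frac{dx}{ds} = \cos\varphi,\qquad
  \frac{dz}{ds} = \sin\varphi,\qquad
  \frac{d\varphi}{ds} = 2b + cz - \frac{\sin\varphi}{x},$$

with $x$ the radial coordinate, $z$ the depth below the apex,
$\varphi$ the tangent angle, $b$ the apex curvature (1/m) and
$c = \rho g / \sigma$ the capillary parameter (1/m²). At the apex
the last term has the limit $d\varphi/ds \to b$.

Implementation choices:

* **Independent variable.** The system is integrated with $\varphi$
  as the independent variable (`deSolve::lsoda`), which is valid
  while $\varphi$ increases monotonically — always the case for
  sessile shapes up to 180° — and makes truncation at a target
  contact angle exact rather than an interpolation afterthought. A
  non-monotone $\varphi$ (re-entrant shape) surfaces as an explicit
  error naming the arc position.
* **Apex start.** Integration starts at $\varphi_0 = 10^{-5}$ on the
  osculating sphere of radius $1/b$; the series error committed is
  $O(\varphi_0^3)$ and invisible at the default tolerances
  (`rtol = 1e-9`).
* **Volume.** $V = \int \pi x^2\,dz$ by trapezoid over the (dense)
  arc samples. With 400 samples the spherical-cap closed forms are
  reproduced to better than $10^{-5}$ relative; the test suite
  enforces $10^{-4}$ across curvatures and angles.
* **Sign conventions.** $z$ increases downward from the apex inside
  the solver (the conventional form) and is converted to
  height-above-baseline at the interface. Gravity is fixed at
  9.81 m/s² and enters with the sessile sign: at fixed volume and
  angle it widens and lowers the drop, the familiar flattening.
  Functions accept `g = 0` for the spherical-cap limit.

The inverse problem (`solve_for`) brackets $b$ around the
spherical-cap inverse
$b_0 = \left(\pi(1-\cos\theta)^2(2+\cos\theta)/3V\right)^{1/3}$ and
root-finds with `uniroot`; the round-trip volume error is below
0.1%.

## Imaging: contours and contact angles

Side-view frames are high-contrast (the experimental droplets are
dyed), so a global Otsu threshold on the region above the baseline
is sufficient; the largest dark component touching the baseline is
the droplet. Each column's upper boundary is refined to subpixel by
linear interpolation of the intensity crossing. The baseline itself
is the row maximizing the horizontally integrated vertical gradient,
ties broken to the bottom-most row, with a prominence guard that
turns degenerate images into errors rather than nonsense.

**Contact angles** are the one place the upstream experimental
literature leaves genuinely open (published devices rarely state
their algorithm). The package uses the conventional
polynomial-tangent estimator: a quadratic fit to each flank over the
points within 15% of the drop height, tangent evaluated at the
baseline. Two details matter:

* The quadratic is fit as $r(z)$, not $z(r)$, so the estimator stays
  well conditioned through 90° (vertical tangent) — the angle is
  $\mathrm{atan2}(1, dr/dz)$, mapping smoothly over (0°, 180°).
* No contour smoothing is applied by default; smoothing biases
  tangent estimates at exactly the point of interest.

Round-trip accuracy against the generator is within 2° for angles,
2 px for lengths and heights, at noise up to 5/255 — the property
tests sweep this.

## Volume by profile fitting

The instantaneous volume of an evaporating drop is estimated by
fitting the measured side profile to the Young–Laplace solution,
with volume as the fitting parameter. Real evaporating drops are not
perfectly axisymmetric; the package's declared reconciliation is to
**symmetrize first** (average the two flanks about the midpoint of
the contact points) and report the residual, flagging profiles whose
rms misfit exceeds 5% of the drop height. The fit itself is a
deterministic golden-section search over the apex curvature $b$
(bracket from the spherical-cap inverse of the measured length and
height, fixed ×4 expansion if the optimum lands on an edge),
minimizing the rms *horizontal* distance between measured and model
flanks at matched heights — well defined for the single-valued
flanks of the sub-90° drops this workflow targets. The implied
contact angle at the truncation height is reported alongside
(`theta_implied`) rather than being pinned to the measured angle,
since the two estimates agree only up to measurement error.

One behavior worth knowing: for very flat drops (θ below ~15°) the
horizontal residual is amplified by $\cot\theta$, so the 5%-of-height
advisory can fire even when the fitted volume is accurate to a
fraction of a percent. The flag is informational, not an error.

## Evaporation kinetics

Volume against time is fit by ordinary least squares. The default
window is 0–3000 s: past 50 minutes so little liquid remains that
volume readings flatten into noise and the linear regime ends; the
window is configurable and `window = NULL` uses all points.
$R^2$ of a zero-variance response is defined as 0. Depinning is
declared at the earliest time either edge has moved inward by more
than 2% of the initial length for at least 2 consecutive frames —
the 2%/2-frame defaults sit just above the ≤2 px round-trip
measurement noise, since no published threshold exists. The detector
is translation invariant by construction.

## Forced wetting and retention quantities

The rotation ramp maps speed to tangential acceleration,
$a_T = (2\pi\,\mathrm{RS}/60)^2 r$ with $r = 0.25$ m the droplet's
radial distance. Event detection mirrors how the plots are read:

* **Spreading onset**: first speed at which the front edge has
  advanced by more than 2% of the initial length, 2-frame
  persistence.
* **Advancing angle** θ_a: mean front angle over the frames past the
  onset where the sliding-window slope (5 frames) is below
  0.1°/rpm.
* **Sliding onset / receding angle**: symmetric on the rear edge and
  rear angle. A rear edge that never moves is the permanently pinned
  regime: `rs_slide` is `NA` and θ_r is the final rear-angle
  plateau. When a pinned drop is instead squeezed out of the field
  of view, the disappearance speed may be supplied and is used as
  the critical speed — disappearance is treated as the sliding
  event.

From the critical speed: $Bo_T = \rho L^2 a_T/\sigma$ with
$L = 1$ mm the characteristic length (the $L^2$ makes the group
dimensionless), $F_s = \rho V a_T$ with $V$ the volume at the start
of the ramp (the physically meaningful mass after partial
evaporation; configurable), and the Furmidge factor
$k = F_s / (R\sigma(\cos\theta_r - \cos\theta_a))$ evaluated with
both characteristic lengths: the initial droplet length ($k_1$) and
the length at sliding ($k_2$). The identity
$k_1 L_\mathrm{initial} = k_2 L_\mathrm{sliding}$ holds to machine
precision and is tested.

## Rheology

Power-law fits are linear least squares of $\ln\eta$ on
$\ln\dot\gamma$ (slope $n-1$, intercept $\ln K$) — the field
convention, matching the straight-line appearance of shear-thinning
flow curves on log–log axes. At least 4 points spanning half a
decade are required. `classify_newtonian` calls $|n-1| \le 0.1$
Newtonian, the sensible reading of "viscosity variation within
instrument sensitivity".

## Live/dead counting

Each channel is thresholded (Otsu), labelled, and any connected
component larger than the cell-size maximum — i.e. a merged cluster —
is split by a watershed on its distance transform (EBImage); objects
with area in 10–30 px² are retained. Applying the watershed only to
oversized components keeps single thin rods intact (a watershed on
every component oversegments elongated cells whose distance ridge
carries several shallow maxima). The default pixel scale, 0.566 μm
per pixel edge, is back-derived from the equivalence
10 px² = 3.2 μm². Condition comparison is the one-tailed unpaired
Student's t-test with pooled variance (Welch behind a flag),
significant at p < 0.005; under the null with normal data this level
is exact, and a 10⁴-experiment simulation in the test suite confirms
the rejection rate.

## The synthetic-data generator

The generator exists so that every stage has a ground-truthed input:

* **Sessile images**: the rendered silhouette *is* the
  Young–Laplace solution for the requested (V, θ) — 35 μL at 40° is
  the canonical case — rasterized with 4×4 supersampling, dark drop
  (0.1) on light background (0.9) over a darker substrate, additive
  clipped Gaussian noise, 8-bit quantization. Identical seeds give
  bit-identical images.
* **Evaporation series**: volumes exactly affine in time
  ($v_0 = 29.9$ μL and slope $-10^{-2}$ μL/s for the medium-like
  series; slope $-5.6\times10^{-3}$ μL/s for the suspension-like
  series). `pinned` holds the contact radius and lets θ fall;
  `depinning` pins until θ reaches a threshold (default 25°), then
  holds θ and shrinks the length. Parameter sets that would drive θ
  below 2° fail before rendering.
* **Rotation ramps**: piecewise-linear angle trajectories reaching
  the advancing plateau (53° at 40 rpm in the canonical case) and
  receding plateau (15° at 50 rpm), edges moving at 5% of the
  initial length per rpm past their onsets, one frame per rpm at
  1 rpm/s; a permanently-pinned-rear mode holds the rear edge at
  every speed. Rendering of asymmetric frames uses a cubic profile
  honouring both contact angles (optional; event detection consumes
  the geometry).
* **Flow curves**: $\eta = K\dot\gamma^{n-1}$ over 10–100 s⁻¹,
  log-spaced, multiplicative Gaussian noise.
* **Cell fields**: 3:1-aspect ellipses ("rods"), rasterized areas
  constrained to 10–30 px², non-overlapping placement with a 2 px
  guard band, exact per-channel counts and areas recorded.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: optical artefacts
(reflection, meniscus lensing, depth of field), motion blur,
non-axisymmetric evaporation shapes beyond the symmetrize-and-flag
treatment, bacterial sedimentation patterns within the drop,
overlapping or out-of-focus cells, and any internal-flow physics.
The generator's defaults are the study conditions, not tuning knobs.

## Problem sizes and determinism

The test suite renders droplets at 0.01 mm/px (a ~8 mm drop spans
~800 px), uses 10-seed medians for stochastic round trips, 20 seeds
for rheology noise, and 10⁴ simulated experiments for the t-test
level — sizes at which all checks run comfortably on one CPU. All
randomness flows through explicit integer seeds; the generators
restore the caller's RNG state.

## Known limitations

* Silhouette rendering and profile extraction assume θ ≤ 90°
  (single-valued flanks per column); the experimental systems this
  targets sit well below that.
* The evaporation-series generator solves a nested root problem per
  frame (θ from the pinned radius, then b from the volume); it is
  accurate but not fast — about a second per frame — so long series
  are best generated with `render = FALSE` unless images are needed.
* `detect_events` assumes the force points toward increasing edge
  coordinates and frames ordered by speed.
* The Bond number uses $L^2$; a first-power characteristic length
  would leave the group dimensional, so the package does not offer
  it.
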