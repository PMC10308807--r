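# dropwet

Quantitative analysis of sessile-droplet wetting for bacteria-laden
suspensions: how droplets of microbial culture evaporate on a
substrate, and how strongly the partially evaporated droplets resist
sliding when a tangential (centrifugal) force is ramped up. The
retention force is an indirect measure of early bacterial adhesion —
the precursor of biofilm formation on food-industry and clinical
surfaces.

The package covers the full measurement chain:

- **Drop shape.** Numerical solution of the axisymmetric
  Young–Laplace equation in Bashforth–Adams form,
  `dφ/ds = 2b + cz − sin φ / x` with `c = ρg/σ`, plus the inverse
  problem (apex curvature from volume and contact angle).
- **Imaging.** Baseline detection, subpixel droplet contour
  extraction from side-view images, polynomial-tangent contact
  angles, and top-view footprint contours.
- **Volume fitting.** Instantaneous droplet volume estimated by
  fitting the measured side profile to the Young–Laplace solution,
  the volume being the fitting parameter.
- **Evaporation kinetics.** Linear volume-decay fits `v(t) = v₀ + kt`
  with R², normalized length/height trajectories, and contact-line
  depinning detection.
- **Forced wetting.** Event detection on rotation-ramp series
  (spreading onset, sliding onset, advancing/receding plateaus
  θ_a/θ_r), tangential acceleration `a_T = ω²r`, tangential Bond
  number `Bo_T = ρL²a_T/σ`, retention force `F_s = ρV·a_T`, and the
  Furmidge retention factor `k = F_s / (Rσ(cos θ_r − cos θ_a))`.
- **Rheology.** Power-law (shear-thinning) fits
  `η = Kγ̇ⁿ⁻¹` in log–log space, Newtonian classification.
- **Viability.** Live/dead cell counting by threshold + watershed +
  size filter, per-area densities, one-tailed pooled t-test at
  p < 0.005.
- **Synthetic data.** A generator for every input above —
  Young–Laplace-shaped droplet images, evaporation series, rotation
  ramps, flow curves, two-channel cell fields — with exact ground
  truth, so every stage is testable end to end without external
  data.

## Worked example

Render a 35 μL droplet at 40° contact angle, measure it back, and
refit its volume:

```r
library(dropwet)
medium <- fluid_properties(997, 0.072)          # rho kg/m^3, sigma N/m
g <- gen_sessile_image(35, 40, medium,
                       synthetic_scene(noise_sd = 5/255, seed = 42))
geom <- measure_frame(g$image, 0.01)            # 0.01 mm per pixel
fit_volume(geom$profile, medium)
```

```
theta_left = 40.4 deg, theta_right = 40.1 deg
length = 8.05 mm, height = 1.26 mm
<volume_fit> V = 34.993 uL, b = 120.6 1/m, theta = 40.0 deg, rms = 0.0068 mm
```

The measured angles sit within half a degree of the 40° ground
truth, and the Young–Laplace volume fit recovers 35 μL to 0.02%
despite the added camera noise. `b` is the fitted apex curvature and
`rms` the flank misfit (large values flag non-axisymmetric drops).

A forced-wetting run — ramp to 100 rpm at 1 rpm/s, droplet 25 cm from
the axis — and its retention quantities:

```r
rf <- gen_rotation_ramp(list(theta_adv = 53, rs_spread = 40,
                             theta_rec = 15, rs_slide = 50))
detect_events(rf, fluid = medium, volume = 35)
```

```
<wetting_events>
  theta_adv = 53.0 deg, theta_rec = 15.0 deg
  spreading at 41 rpm, sliding at 51 rpm
  aT = 7.13 m/s^2, Bo_T = 0.0987, F_s = 0.000249 N, k1 = 1.58, k2 = 1.05
```

Spreading and sliding onsets are recovered one frame (1 rpm) after
the true onsets at 40 and 50 rpm; the advancing/receding plateaus are
exact. `F_s` is the sliding retention force, `k1`/`k2` the Furmidge
factors computed with the initial and at-sliding droplet lengths
(`k1·L_initial = k2·L_sliding` by construction).

A shear-thinning flow curve with 5% measurement noise:

```r
fit_power_law(gen_flow_curve(K = 0.05, n = 0.4, noise_rel = 0.05, seed = 1))
```

```
K = 0.0484 Pa.s^n, n = 0.411, R^2 = 0.9932
```

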