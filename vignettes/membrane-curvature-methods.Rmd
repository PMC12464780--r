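---
title: "Methods: monolayer thermodynamics, lateral pressure moments, and surface curvature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monolayer thermodynamics, lateral pressure moments, and surface curvature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcurve)
```

memcurve quantifies how the ceramide (CER) / sphingomyelin (SM) ratio
shapes the elasticity and curvature of matrix-vesicle membrane models.
It has three analysis layers — Langmuir isotherm thermodynamics, elastic
constants from lateral pressure profiles, and bilayer surface geometry —
plus a synthetic-data layer that generates inputs with closed-form ground
truth for all of them. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic fixtures do and
do not demonstrate about real data.

## Isotherm thermodynamics

A Langmuir π–A isotherm records surface pressure π (mN/m) against mean
molecular area A (Å² per molecule) during monolayer compression.
`isotherm()` canonicalises raw curves by sorting to strictly decreasing
area and averaging exact duplicate areas; hysteresis branches must be
split by the caller, because compression and expansion are physically
different curves and averaging them would be meaningless.

**Excess molecular area.** For a binary CER/SM mixture with mole
fractions $X_{CER} + X_{SM} = 1$,

$$A_{exc}(\pi) = A_{mix}(\pi) - \left[ A_{CER}(\pi)\,X_{CER} + A_{SM}(\pi)\,X_{SM} \right].$$

Negative values mean the mixture packs more tightly than additivity
predicts (attractive CER–SM interactions); positive values mean repulsion;
zero is ideal mixing. Because measured isotherms never share pressures
exactly, all multi-isotherm operations interpolate areas onto an explicit
common pressure grid (default 200 uniform points over the shared range).
Interpolation is monotone linear in π; requests outside the sampled range
raise an error rather than extrapolate.

**Excess Gibbs energy.**

$$\Delta G_{exc}(\pi) = N_A \int_0^{\pi} A_{exc}\, d\pi',$$

evaluated by composite trapezoid quadrature. Units stay in (mN/m, Å²)
end-to-end; the single conversion constant 1 Å²·mN/m per molecule
= 6.02214076 J/mol is applied inside this integral only, which keeps unit
bookkeeping auditable. Isotherms rarely reach π = 0, so the integrand is
extended downward either by holding the lowest-pressure value constant
(default) or by linear extrapolation of the first two grid points
(`extend = "linear"`); the choice matters only below the lowest measured
pressure and is recorded in the result.

**Compressibility modulus.**

$$C_s^{-1}(\pi) = -A_\pi \left( \frac{d\pi}{dA} \right)_T.$$

The derivative is estimated by a local polynomial least-squares fit at
each sample (default window 11 points, order 3) — the Savitzky–Golay
estimator generalised to non-uniform area grids, which canonicalised
noisy isotherms produce. Window and order are echoed in the result. On
noiseless analytic fixtures the estimator is exact for polynomials up to
the fit order, which is what the closed-form tests exploit; on noisy data
a wider window (e.g. 31 points, order 2) trades bias for variance.
Phase-state classification uses the classical monolayer thresholds
0–12.5 gaseous, 12.5–50 liquid-expanded, 50–100 transitional, 100–250
liquid-condensed, > 250 mN/m solid, all configurable; non-finite values
are flagged `unclassified` rather than erroring. Because no read-off
pressure convention is universal, `compressibility_modulus()` returns the
full $C_s^{-1}(\pi)$ curve and pipeline reports include both the curve
and its maximum; pick the convention your data require.

## Lateral pressure profile and elastic constants

MD post-processing yields the diagonal stress components on a uniform z
grid. The lateral pressure profile is

$$LPP(z) = \tfrac{1}{2}\left[ P_{xx}(z) + P_{yy}(z) \right] - P_{zz}(z),$$

with no smoothing applied. Inputs are pressure-tensor components as MD
engines report them; no virial-sign flip is applied — a stress-vs-pressure
sign confusion negates both moments, so check your exporter's convention.

The elastic constants are z-moments of the centred profile:

$$K_C c_0 = \int_{d_-}^{d_+} z\, LPP(z)\, dz, \qquad
  \bar K_G = -\int_{d_-}^{d_+} z^2\, LPP(z)\, dz.$$

$K_C c_0$ (the spontaneous bending moment) is reported in bar·nm² and pN
(1 bar·nm² = 0.1 pN); $\bar K_G$ in bar·nm³ and $k_B T$
(1 bar·nm³ = 10⁻²² J) at an explicitly supplied temperature (default
303.15 K, a common simulation temperature). $K_C$ and $c_0$ are never
separated: only their product is determined by the first moment.

**Numerical choices.**

* *Quadrature*: composite trapezoid on the native grid. Stress profiles
  are already binned averages; higher-order rules add no information, and
  for smooth, rapidly decaying integrands the trapezoid rule converges
  superalgebraically, so 512 points recover Gaussian-bump closed forms to
  machine precision.
* *Midplane*: the integrals assume z = 0 at the membrane midplane.
  The default locator takes the midpoint between the two outermost
  zero-crossings of LPP, falling back to the geometric centre of the
  1%-support when fewer than two crossings exist; the applied shift is
  recorded and centring is idempotent.
* *Bounds*: the default rule takes the outermost nodes where |LPP|
  exceeds f = 0.01 of its maximum, padded one grid step. This keeps
  bulk-water noise out of the moments, at the cost of cutting Gaussian
  tails worth roughly 0.2–0.3% of the second moment; use `f = 0.001` or
  `rule = "full"` when the profile is clean and sub-0.1% fidelity
  matters. Bounds must bracket z = 0 ($d_- < 0 < d_+$); explicit user
  bounds are honoured verbatim.
* *Degenerate input*: an identically zero profile refuses centring and
  bound detection with a diagnostic; $c_0 = 0$ in `curvature_radius()`
  returns `Inf` (a flat membrane), not an error.

## Surface geometry of simulated bilayers

Each leaflet is represented by one reference point per lipid (a head
bead or atom chosen by the caller — the package never parses lipid
chemistry) in a laterally periodic box. `fit_surface()` estimates the
leaflet height field on a node-centred nx × ny grid by Gaussian-kernel
regression with minimum-image distances, so the fitted field is periodic
by construction and deterministic for fixed inputs. The default
bandwidth is 1.5× the mean nearest-neighbour spacing estimate
$\sqrt{L_x L_y / N}$; smaller bandwidths reduce smoothing bias (a
sinusoid of wavelength L is attenuated by
$\exp[-(2\pi b / L)^2 / 2]$) but amplify sampling noise — the package
records a warning when the bandwidth falls below the spacing estimate.

Normals come from central differences with periodic wrap and are
oriented to non-negative z, so leaflet orientation cannot flip signs.
The curvature order parameter is the area-weighted mean of the second
Legendre polynomial of the normal's z-cosine,

$$S_C = \left\langle \tfrac{1}{2}\left( 3\cos^2\theta - 1 \right) \right\rangle_A,$$

with area elements $\sqrt{1 + h_x^2 + h_y^2}\,dx\,dy$. This convention
reproduces the planar calibration ($S_C = 1$ iff θ ≡ 0) and decreases
monotonically with sinusoid amplitude at fixed wavelength. Area per
lipid is reported in both conventions — projected ($L_x L_y / N$) and
surface (triangulated fitted area / N, never below projected) — since
published values do not always say which was used. Head-to-head
thickness $D_{HH}$ is the grid mean of the upper-minus-lower height
difference; crossing nodes are counted and flagged.
`trajectory_summary()` reports per-frame $S_C$, $A_L$, $D_{HH}$ and
mean/median/IQR over a configurable trailing window, the statistics
behind per-composition violin plots.

## The synthetic-data layer

Every generator declares its ground truth analytically:

* **Isotherms** — linear, hyperbolic, or piecewise-linear with a
  low-slope plateau segment (phase-transition emulation), sampled on a
  uniform area grid with optional additive Gaussian pressure noise.
  Mixture families are built as
  $A_{mix}(\pi) = X A_1(\pi) + (1-X) A_2(\pi) + A_{exc}(\pi)$ with a
  declared polynomial excess function, so `excess_area()` must recover
  the declared function up to interpolation error.
* **Stress fields** — sums of Gaussian bumps, whose first and second
  moments have closed forms ($a\sigma\sqrt{2\pi}\,\mu$ and
  $a\sigma\sqrt{2\pi}(\mu^2+\sigma^2)$ per bump); the grid must span
  every centre by ≥ 5 widths so truncated moments match the
  infinite-range forms. The bundled three-regime default places, per
  leaflet, a positive headgroup bump, a negative interfacial trough and
  a positive chain bump; the "asymmetric" variant doubles the
  outer-leaflet amplitudes, mirroring enzymatically generated leaflet
  asymmetry as an *ordering* fixture (larger bending moment, more
  negative Gaussian modulus than the symmetric control), not a numeric
  reconstruction of any measured membrane.
* **Surfaces** — plane, uniformly tilted normal field, sinusoid
  (wavelength must divide the box), or plane-plus-spherical-cap bud
  (footprint must fit in half the box), sampled uniformly in (x, y) and
  lifted to the surface, mimicking in-plane lipid disorder without
  modelling diffusion. Each cloud carries the oracle $S_C$ from dense
  quadrature of $P_2$ over the analytic surface.

Noise models are additive Gaussian on pressures and stresses and
positional Gaussian jitter on coordinates — the simplest controllable
choices, with magnitudes left as free parameters (trough noise
magnitudes are instrument-specific). All generators take a `seed` and
are bitwise reproducible.

**Study conditions baked into the pipeline's synthetic stage.** The pure
isotherms are linear and anchored to measured 25 mN/m molecular areas of
41 Å² (CER, π = 66 − A) and 54 Å² (SM, π = 92.5 − 1.25A); the equimolar
mixture carries a constant −7.5 Å² excess, reproducing the measured
40 Å² equimolar area versus the 47.5 Å² ideal value. The stress stage
uses the three-regime field at 512 points over [−4, 4] nm; the surface
stage a 0.5 nm-amplitude, 10 nm-wavelength sinusoid with 512 lipids per
leaflet and 0.05 nm jitter in a 10 × 10 nm box. These were chosen once
as representative of the measured systems and are not tuned.

**What passing tests show — and don't.** The fixtures certify the
numerics: definitional identities, closed-form moments, declared-excess
recovery, and convergence. They do not emulate correlated trough drift,
finite-size undulation spectra, force-field artefacts, or lipid
conformational detail; agreement on fixtures therefore validates the
analysis path, not any particular simulation or measurement.

## Worked example

```{r example, eval = FALSE}
# equimolar CER/SM excess area from pure isotherms anchored at 25 mN/m
grid <- seq(5, 40, length.out = 141)
cer <- isotherm(seq(64, 20, length.out = 141), 66 - seq(64, 20, length.out = 141))
sm_a <- seq(72, 30, length.out = 141)
sm  <- isotherm(sm_a, 92.5 - 1.25 * sm_a)
mix <- isotherm(0.5 * (66 - grid) + 0.5 * (92.5 - grid) / 1.25 - 7.5, grid)
ex <- excess_area(mix, cer, sm, mixture_spec(0.5), grid = grid)
ex[ex$pressure == 25, ]          # A_ideal 47.5, A_mix 40, A_exc -7.5
excess_gibbs_energy(ex, 25)      # -1129.15 J/mol

# elastic constants of a single Gaussian stress bump
m <- stress_field_model(data.frame(amplitude = 100, center = 1, width = 0.2),
                        z_range = c(-3, 3))
gs <- gen_stress_profile(m)
prof <- compute_lpp(gs$stress)
elastic_constants_from_lpp(prof, detect_bounds(prof, rule = c(-3, 3)))
# bending moment 5.013 pN; Gaussian modulus -52.14 bar nm^3 = -1.246 kB*T
```

## Known limitations

* No monolayer-to-bilayer pressure mapping, equation-of-state fitting, or
  hysteresis analysis; isotherm branches must be pre-split.
* No computation of stress tensors from trajectories; the package
  consumes post-processed profiles.
* $K_C$ and $c_0$ are not separable from the first moment alone.
* No principal/Gaussian curvature maps or lipid-domain detection; the
  surface layer measures global descriptors only.
* Trajectory input is an ordered list of single-frame text files; binary
  trajectory formats are out of scope.

Test problem sizes (up to 20 000-point clouds, 64 × 64 grids, 512–4096
point stress grids) were chosen so the full suite certifies convergence
while running in seconds.
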