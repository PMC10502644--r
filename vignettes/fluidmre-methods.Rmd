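---
title: "Methods: tissue fluidity, stiffness and tumour growth patterns from MRE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue fluidity, stiffness and tumour growth patterns from MRE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidmre)
```

## The model

Magnetic resonance elastography (MRE) drives harmonic shear waves into
tissue and recovers its complex shear modulus $G^* = G' + iG''$. Two
scalar summaries organise everything this package does:

* **Stiffness**, expressed either as $|G^*|$ (Pa) or as the shear-wave
  speed $c$ (m/s). The two are interconvertible through
  $|G^*| = c^2 \rho \,(1 + \cos\varphi)/2$ with the soft-tissue
  convention $\rho = 1000\ \mathrm{kg/m^3}$ (1 kg/l). In the elastic
  limit this is the familiar $|G^*| = \rho c^2$.
* **Fluidity**, the normalised phase angle
  $(\varphi - \pi/4)/(\pi/4)$ with $\varphi = \arctan(G''/G')$. It runs
  from $-1$ (pure solid) through $0$ (the solid--fluid transition, where
  storage and loss moduli balance) to $+1$ (pure liquid). Fluidity is
  *not* water content: it measures whether constituents (cells,
  matrix segments) can change position and dissipate shear stress.

The package treats tumours as materials whose progression leaves a
mechanical fingerprint: malignant transformation tends to raise both
stiffness and fluidity relative to host tissue (brain tumours being the
notable inversion), and unjamming of cancer-cell clusters fluidizes
tissue locally, producing spatially heterogeneous fluidity maps and, at
an unstable front, diffuse or fingered boundaries.

## Springpot dispersion fitting (`fit_springpot`)

Tabletop measurements of cylindrical gel samples yield a complex
wavenumber $k^* = k' + ik''$ per drive frequency, hence speed
$c = 2\pi f / k'$ and penetration rate $a = f/k''$. These dispersions
are summarised by a two-parameter springpot (fractional element)

$$G^*(f) = \mu^{1-\alpha} \eta^{\alpha} (i 2\pi f)^{\alpha},
\qquad \eta \equiv 1\ \mathrm{Pa\,s},$$

which interpolates between a spring ($\alpha = 0$) and a dashpot
($\alpha = 1$) and whose phase is frequency independent:
$\varphi = \alpha\pi/2$. Fixing $\eta$ removes the scale degeneracy
between $\mu$ and $\eta$.

Numerical choices:

* **Objective.** Joint *relative* least squares on $(c(f), a(f))$
  rather than on complex $G^*$, matching the measurement pipeline's
  order (wavenumbers are fitted first, then converted). Relative
  residuals keep the two channels, which differ by orders of
  magnitude, commensurate. Lossless entries ($k'' = 0$, penetration
  infinite) contribute only a speed residual; fitted $k''$ below
  $10^{-9} k'$ is snapped to the lossless limit to avoid astronomically
  large but meaningless penetration rates destabilising the fit.
* **Initialisation.** Closed form: $\alpha_0 = 2\bar\varphi/\pi$ from
  the median per-frequency phase implied by $2\,\mathrm{atan}(k''/k')$,
  and $\mu_0$ by solving the springpot magnitude at the median
  frequency. This warm start sits close enough to the optimum that the
  bounded quasi-Newton refinement (`nlminb`, $\alpha \in [0,1]$,
  $\log\mu$ parameterisation) does not wander into local minima.
* **Report point.** Summaries are evaluated at 500 Hz, the midpoint of
  the 200--800 Hz fitting band used for gel samples; acquisitions cover
  200 Hz--2 kHz in 100 Hz steps and out-of-band frequencies are kept in
  the dispersion table but excluded from the fit.

## Cylinder profile inversion (`fit_cylinder_profile`)

Axial shear waves in a z-infinite driven cylinder follow
$u(r) = U_0 J_0(k^* r)/J_0(k^* R)$. The package evaluates $J_0$ at
complex argument by the midpoint rule on
$J_0(z) = \frac{1}{\pi}\int_0^\pi \cos(z \sin\theta)\,d\theta$
(256 nodes), which is spectrally convergent for this entire integrand
and machine-accurate over the whole wavenumber range the fitter
explores ($|z| \lesssim 70$); base R's `besselJ` is real-only.

The inverse problem is multimodal in $k'$ (Bessel lobes), so a
log-spaced grid over $k' \in [\pi/2R,\ 20\pi/R]$ crossed with
$k''/k' \in \{0.05, 0.2, 0.5\}$ seeds a bounded local refinement. The
residual stacks real and imaginary parts -- magnitudes alone would
discard the phase information that pins $k''$ -- and the complex drive
amplitude $U_0$ is solved linearly at every candidate, so it never
enters the nonlinear search. Solutions with $|J_0(k^*R)| < 10^{-6}$
(resonances of the lossless problem) are rejected, as are fits pinned
at the $k'$ box; a fit pinned at $k'' = 0$ is the legitimate elastic
limit and is kept.

## Desk-scale wave simulation and inversion

The forward model is the scalar heterogeneous Helmholtz equation
$\nabla^2 u + \rho\omega^2/G^*(x,y)\, u = 0$ -- not full
elastodynamics, because the inversion identity under test is itself
scalar-Helmholtz based. A unit Dirichlet drive occupies one edge;
the other edges carry an 8-pixel sponge (quadratic ramp of an imaginary
perturbation to the squared wavenumber, peak strength 3) backed by
zero Dirichlet, which suppresses reflections well enough that interior
medians are unbiased. The sparse complex system is solved exactly via
an equivalent real block system (`Matrix`), so discrete residuals are
at direct-solver level ($\sim 10^{-10}$).

The multifrequency inversion is a magnitude-representation direct
solve: with $\Delta$ the spacing-aware 5-point Laplacian of Gaussian
pre-smoothed fields ($\sigma = 1$ px, mirroring standard practice since
the Laplacian amplifies noise),

$$|G^*| = \rho\,\frac{\sum_f \omega_f^2 |u_f|}{\sum_f |\Delta u_f|},
\qquad
\varphi = \arccos\!\left(\frac{-\sum_f \mathrm{Re}(\Delta u_f
\overline{u_f})}{\sum_f |\Delta u_f||u_f|}\right),$$

with the arccos argument clamped to $[0,1]$ so noisy pixels stay in
the physical phase range. A two-pixel margin and pixels with Laplacian
energy below $10^{-9}$ of the map maximum are masked. Both estimators
are ratios of homogeneous-degree-one quantities, so the maps are
exactly invariant to a common complex rescaling of all fields. The
published multifrequency estimator formulas live in inversion papers
whose pipelines are out of scope here; the forms above are
reconstructed from their magnitude-representation description, and the
package relies on forward--inverse self-consistency rather than
bit-level agreement with clinical pipelines. The companion
`gradient_speed_map` is a deliberately simplified surrogate for
wavenumber-based inversions: local wavenumber from
$|\nabla \arg u| = |\mathrm{Im}(\bar u \nabla u)|/|u|^2$ (no phase
unwrapping needed), amplitude-weighted frequency compounding.

## Fluidity-map features

* **Regimes.** Fluidity below $-0.1$ is `solid`, above $+0.1$ `fluid`,
  `transitional` between. The $\pm 0.1$ defaults reproduce every
  unambiguous regime label of the packaged cohort from its group mean;
  they are configuration, not constants -- a clinically validated cut
  (e.g. by ROC analysis) may replace them. An optional reporting
  convention marks means within $0.03$ of a threshold with a dual
  label; two cohort controls carry printed dual labels (means $-0.26$
  and $-0.17$) that no such numeric convention reproduces, so those are
  carried verbatim and never pivot any classification.
* **Heterogeneity.** Shannon entropy (nats) of the three regime
  occupancy fractions within the ROI, flagged heterogeneous when at
  least two regimes each hold $\ge 10\%$. Occupancy-based scoring
  depends only on fractions, making it invariant to spatial shuffling
  and robust across resolutions; the underlying concept (fluid islands
  in a solid backbone) names no formula, so this operationalisation is
  the package's own.
* **Front texture.** Roughness is the isoperimetric quotient
  $P^2/(4\pi A)$ of the tumour contour; gradient width is the mean
  distance along boundary normals over which fluidity traverses the
  25--75% band of the tumour--background contrast. The front is
  `diffuse` when roughness $> 1.5$ *or* width $> 3$ px -- an
  OR-combination because fingering and blurring are distinct
  infiltration signatures and sensitivity is preferred. Masks are
  pre-smoothed with a 1 px Gaussian before marching-squares contouring:
  raw binary contours overestimate a digitized disk's roughness by
  $\sim$12%, pre-smoothing reduces that to $\sim$1% (within the 5%
  disk tolerance used in the tests).
* **Interfacial stability.** A softer, more solid tumour pushed into a
  more fluid host (the glioblastoma configuration) satisfies
  $\sin\varphi_t/\sin\varphi_c < |G^*_c|/|G^*_t|$, the Saffman--Taylor
  condition for viscous fingering adapted to tissue phase angles.

## The growth-pattern scheme

Two independent growth modes are read off five categorical inputs
(stiffness ratio, tumour regime, control regime, heterogeneity, front
texture): *displacing growth* (pushing the host aside; requires the
tumour to be stiffer plus mechanically active) and *infiltrative cell
spreading* (cells escaping the boundary; signalled by a fluid regime
or a diffuse front). Types combine as
$\mathrm{type} = 1 + \mathrm{displacing} + 2\cdot\mathrm{infiltrative}$.

The tree is reconstructed from the stated rules -- softer tumours
cannot displace and their type follows the front alone; diffuse fronts
always permit infiltration; heterogeneity implies at least partial
fluid-like behaviour and hence activity -- and validated against every
unbracketed row of the published retrospective table. The control
regime is one of the five stated inputs (the 72-row enumeration counts
it) but never pivots the reconstructed tree; it is carried for
reporting and for the Saffman--Taylor fallback. Inputs marked
redundant are resolved by evaluating all completions; when the front
is redundant and moduli are supplied, interfacial stability decides,
otherwise a dual-type answer (or, optionally, an error) results.
Transitional tumours in the stiffer branch carry a "type 2/4"
annotation -- transitional tissue can exhibit both traits -- but the
tree output remains the deterministic type. Bracketed corrections in
the published table (haemangioma 4$\to$2, meningioma 1$\to$2,
glioblastoma 3$\to$4) encode clinical knowledge external to the scheme
(e.g. T2-hyperintensity, oedema-mediated displacement) and are
reported as annotations, never as tree output.

The stiffness-ratio input is operationalised from group summaries as
"tumour mean exceeds control mean *and* Welch's t-test from the
summary statistics rejects at $\alpha = 0.05$" -- the benign adenoma
(means 1.41 vs 1.38 m/s) is thereby correctly *not* stiffer while the
cholangiocarcinoma (2.57 vs 1.72) is.

## What the generators emulate (and what they do not)

* `make_dispersion` / `make_cylinder_profiles`: springpot media probed
  on the tabletop protocol grid (200 Hz--2 kHz, 100 Hz steps, 4 mm
  radius, 64 radial samples). Noise is multiplicative lognormal on
  dispersion magnitudes and additive complex Gaussian on profiles --
  the standard MR magnitude/complex idioms. The named gel scenarios
  pin springpots to measured (speed, fluidity) pairs at 500 Hz:
  rat-tail collagen (0.542 m/s, $-0.176$), bovine-skin collagen
  (0.64 m/s, 0.350), crosslinked 1:2 mix (1.09 m/s, $-0.754$).
* `make_phantom`: piecewise-constant truth maps (disk or fingered-star
  inclusion, optional fluid islands covering a target fraction,
  optional Gaussian boundary blur) pushed through the forward solver.
  Islands are random disks of radius $\approx r_0/6$ accumulated until
  target coverage; the generator labels a phantom front `diffuse` when
  it is a star or blurred with $\sigma \ge 3$ px, matching the
  feature-extractor thresholds by construction.
* `make_tracks`: jammed cells are Ornstein--Uhlenbeck walks confined to
  a cage whose stationary 3D RMS displacement is `caged_sd_um`
  (default 3 µm = 0.3 cell radii, correlation time 30 min); unjammed
  cells are persistent random walks (0.25 µm/min, per-frame direction
  persistence 0.9) that traverse several cell radii over the default
  7 h observation imaged every 10 min. The cell radius default of
  10 µm is a typical epithelial value; the caging criterion is stated
  in units of cell radius without a number, so the radius is always
  configurable. Requested mixture fractions are realised exactly
  (`round(n * fraction)`), so estimator error reflects
  misclassification, not binomial sampling.

None of the generators simulate scanner artifacts, phase-unwrapping
failures, physiological motion, 3D wave physics, or segmentation
error. A green forward--inverse test therefore establishes estimator
correctness under the stated noise models, not clinical performance.

## Degenerate inputs and tie-breaks

* Both moduli zero: phase angle undefined, error.
* $k'' = 0$: penetration rate $+\infty$ with a `lossless` flag, not an
  error -- it is the valid elastic limit.
* Zero wave fields: every pixel falls below the validity threshold and
  the inversion raises a classed failure
  (`fluidmre_inversion_failure`) rather than returning an all-`NA`
  map.
* Stroma-tagged tracks: the caging criterion does not apply to single
  cells outside clusters; they return `not_applicable` instead of a
  label. No drift correction is applied before displacements -- none
  is stated for the manual-tracking protocol the data model follows.
* Maximum (not end-to-end) displacement decides jamming, because caged
  motion can end near its start.

## Known limitations

* The scalar 2D simulation cannot probe mode conversion, compressional
  contamination (profiles are assumed pure shear) or through-plane
  effects.
* Numeric agreement with the published clinical inversion pipelines is
  unverifiable here; only forward--inverse self-consistency is
  claimed.
* Scale-downs for test budget: the inversion contrast study runs 10
  noise seeds on a 64-px grid (design: 100 seeds) and the cylinder
  noise study keeps its full 100 seeds; medians are stable under both.
* Growth patterns reflect mechanics-based aggressiveness, not patient
  survival, and the packaged retrospective inputs substitute
  histopathology-derived heterogeneity/front values where imaging
  cannot yet resolve them.

## A worked example

```{r example}
p <- gel_scenario("crosslinked_mix")
profiles <- make_cylinder_profiles(p, noise = 0.02, seed = 1)
pipe <- tabletop_pipeline(profiles)
pipe$summary
classify_growth(stiffer = TRUE, tumor_regime = "fluid",
                control_regime = "transitional",
                heterogeneous = TRUE, front = "sharp")
```
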