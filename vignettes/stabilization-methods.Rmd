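---
title: "Methods: simulated active 3D sample stabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated active 3D sample stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanolock)
```

## The problem and the model

Single-molecule localization at nanometer resolution requires the sample to
stay fixed relative to the objective with sub-nanometer precision for the
whole measurement, while thermo-mechanical drift moves it at up to about
1 nm/s. `nanolock` implements the standard active-stabilization
architecture — fiducial-based lateral locking, reflected-beam focus locking,
PI feedback to a quantized piezo stage — and, because its camera and stage
are reached only through minimal proxy contracts (`acquire()`;
`get_position()` / `set_xy()` / `set_z()`), the identical control code runs
against a *virtual microscope* that renders frames under a known drift
process. Everything below is therefore testable: the loop's residuals can be
compared against the ground truth the simulator injected.

### Image formation

Each fiducial marker and the focus reflection are rendered as
pixel-integrated 2D Gaussians: the expected count in pixel $(i, j)$ is the
analytic integral of the continuous Gaussian over the pixel area (a product
of differences of normal CDFs), not a point sample. This matters when the
spot width is only a few pixels: the integrated model keeps both the
renderer and the fitting model exact, which is also why the package can
demand exact recovery (to $10^{-6}$ px) of noiseless spots in its tests.
Poisson shot noise is applied to the photon signal, then the camera baseline
and Gaussian read noise are added. Pixels are indexed 0-based and a
coordinate denotes a pixel center.

A defocus $\Delta z$ translates the reflected focus spot laterally by
$g\,\Delta z$ along the image x-axis; lateral sample motion leaves the
reflection untouched (the reflecting interface is laterally uniform). That
asymmetry is the physical basis of the decoupled XY and Z channels.

### Localization

Fiducials are fitted with a six-parameter elliptical integrated Gaussian
plus free additive offset (the quasi-dark-field background is low but not
zero; pre-subtracting it would bias positions), by Levenberg–Marquardt with
box bounds. Each frame's fit is seeded by the previous frame's result, as a
real-time implementation would, which cuts iterations to a handful. Failures
return `converged = FALSE` — never an exception — and a failed marker is
re-seeded from image moments, but never contributes a correction. The focus
reflection uses an intensity-weighted center of mass over pixels above 20%
of the ROI maximum, with that threshold level subtracted (plain CoM is
biased by the baseline; the value 0.2 is our documented choice — the
original recipe is not published). $\Delta z$ is the *signed* projection of
the CoM shift onto the calibrated axis times the calibrated response;
using the 2D modulus instead would lose the sign of defocus.

### Control

Each axis carries a PI response
$u = -(k_p e + k_i \int e\,dt)$ with anti-windup clamping, evaluated on the
K-marker average displacement (X, Y) and on $\Delta z$ (Z). Defaults:
$k_p = 0.8$, $k_i = 0$, output limit 50 nm/iteration. The original system
does not publish its gains; proportional-dominant control at the ~54 ms
period converges on a step disturbance in under five iterations, and with
$0 < k_p < 1$ a noiseless step decays geometrically, which the tests assert.
Corrections are issued as **absolute** stage targets (commanded position +
correction) rather than relative jogs, so quantization error cannot
accumulate, and corrections smaller than half the stage quantum (a
dead-band) are not sent, which prevents limit-cycling on the 0.61 nm
lattice. The stage is only commanded between exposures (triggered
acquisition), so a frame never mixes two stage positions. Loop timing is a
virtual clock: runs are deterministic and faster than real time.

### Calibration

Both calibrations move the stage itself as the reference, with stabilization
disabled (the loop would fight the motion):

* **pixel size** — command ≥ 3 lateral positions, localize a fiducial at
  each, regress the stage's *read-back* position (nm) on the measured
  position (px). Using the read-back rather than the commanded value removes
  the quantization error from the regressor, so the noiseless recovery is
  exact. Default steps 0–400 nm in 100 nm increments.
* **axial response** — command ≥ 3 Z positions (default ±100 nm, a ≤ 2.5 px
  reflection shift inside the 31×31 focus ROI), take the CoM at each,
  extract the direction of motion as the principal component and regress the
  projected shift on the realized Z. The response is the inverse slope
  (nm/px), the axis oriented so it is positive; curvature over the range
  would depress $R^2$, which is reported.

The simulation experiments deliberately drive the session with the
*recovered* calibration, not the simulator's ground truth, so calibration
errors propagate into the closed-loop residuals exactly as they would on
hardware.

### Precision statistics

Following standard practice, the headline σ per axis is the width of a
Gaussian fitted to the displacement histogram (Freedman–Diaconis bins — the
binning is our choice, as none is published), with the plain sample standard
deviation always co-reported; for a Gaussian-like trace the two agree within
~15%, and a constant trace rejects the fit and reports sample sd 0.
$\sigma^2_{\mathrm{Stabilization}} = \sigma^2_x + \sigma^2_y$ summarizes the
lateral residual, and
$\sigma_{\mathrm{Total}} = (\sigma^2_{\mathrm{CRB}} +
\sigma^2_{\mathrm{Stabilization}})^{1/2}$ combines it with an externally
supplied Cramér–Rao bound — computing the bound itself requires the
localization-estimator theory of the specific nanoscopy method and is out of
scope.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| fiducial spot width | 184 nm | measured width of a 200 nm AuNP image in NIR dark field |
| pixel size | 80 nm/px | free choice (not published for the reference setups); ~2.3 px per spot σ samples the PSF well |
| exposure | 50 ms | the exposure reported to give suitable fiducial images |
| fiducial photons/frame | 1e5 | sub-nm per-frame localization (σ ≈ 184/√N ≈ 0.6 nm) is required for sub-nm stabilization; realistic for AuNP scattering at 0.3 mW |
| focus photons/frame | 5e5 | a specular laser reflection far outshines scatterers |
| focus spot width | 320 nm | a focused beam reflection, somewhat broader than the fiducial PSF; not characterized in the source system, Gaussian assumed |
| tilt gain g | 2 nm/nm | order unity lever of the tilted-reflection geometry |
| camera | 80×80 px, baseline 100, read noise 2 | small field holding 4 corner fiducials + central reflection |
| drift | v = (0.7, −0.5, 0.4) nm/s, D = 0.05 nm²/s per axis | ~1 nm/s worst-case speed with a few-nm diffusive wander over minutes |
| stage | 20 µm travel, 15 bits, open loop | gives the 0.61 nm quantum |
| loop | 54 ms period, kp 0.8, ki 0, dead-band q/2 | standalone-operation correction period; gains as above |
| ROIs | 11×11 (fiducial), 31×31 (focus) | ≥ ±2σ coverage at σ ≈ 2.3 px; the focus spot is larger |
| detachment | 50 nm from the others' median, 3 consecutive frames | large enough to ignore noise, small enough to catch a loose marker within seconds; sticky until manual reset |

All randomness derives from one session seed through per-component
L'Ecuyer-CMRG substreams (drift and camera noise draw independently), so
runs are bit-reproducible and adding a noise source does not perturb the
others.

## Numerical choices and degenerate inputs

* Stage quantization rounds half to even, avoiding a directional bias on the
  lattice.
* `settle_lag` defaults to 0 (a command is fully realized before the next
  frame), consistent with triggered acquisition; larger values emulate a
  slow stage.
* Fit bounds keep centers inside the ROI and widths positive; a fitted
  amplitude indistinguishable from zero (< 1e−4 of the ROI maximum) is
  declared non-converged rather than reported as a localization.
* Flat, empty or non-finite ROIs fail softly (`converged = FALSE`); an
  all-markers-lost frame pauses lateral correction while Z continues;
  stage command failures are logged and the loop proceeds.
* Ties in the detachment median are irrelevant because the comparison uses
  the Euclidean deviation from the per-component median of the *other*
  markers.

## What the simulation does and does not show

The virtual microscope reproduces the statistical structure that limits a
real stabilization system: shot-noise-limited localization at realistic
photon budgets, multi-marker averaging, actuator quantization, dead-band
limit cycles, drift at ~1 nm/s, and the XY/Z decoupling of the
tilted-reflection focus sensor. The shipped 600-simulated-second run (11111
iterations, ~1.5 min of CPU) holding every axis below 1 nm therefore
demonstrates that the *algorithmic chain* — localization, averaging,
calibration, feedback, quantization handling — supports sub-nanometer
residuals under those conditions, the same bound the hardware system
reports over two hours.

It does not model: aperture/dark-field optics, evanescent-field physics or
Mie scattering (spots are parametric Gaussians); vibration spectra,
acoustic transients or mechanical hysteresis; camera fixed-pattern noise or
nonlinearity; stage creep; or real acquisition-timing jitter. Passing tests
here consequently validate the software loop, not any particular
instrument. Astigmatism-based 3D localization and GUI/hardware drivers are
out of scope by design; σ_CRB is always an external input.

Problem sizes used by the test suite were chosen to keep the full run in a
few minutes while leaving Monte-Carlo error well inside each asserted
tolerance: 600 s for the headline closed-loop run, 1–20 s for loop
properties, 100–10⁴ repetitions for Monte-Carlo checks.
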