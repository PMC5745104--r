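---
title: "Deformation velocity imaging of de-swelling corneas: methods and design"
author: "dvioct authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation velocity imaging of de-swelling corneas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dvioct)
```

This vignette is the package's own account of the science it implements:
the measurement model, the segmentation and averaging machinery around it,
the osmotic de-swelling model, the synthetic phantoms everything is
validated on, and the design decisions taken where the method left choices
open.

## 1. The measurement model

A Fourier-domain OCT pixel is a complex number whose argument (the Fourier
phase) advances by $4\pi n_G \Delta z/\lambda$ when the scatterers inside
it move axially by $\Delta z$ in a medium of group index $n_G$. The phase
of a single pixel is therefore an interferometric displacement gauge with
nanometre sensitivity, but it is only defined modulo $2\pi$ and it responds
equally to motion of the sample as a whole. Deformation velocity imaging
(DVI) handles both problems at once:

1. **Referencing.** Per A-scan, a reference pixel is chosen as the
   amplitude maximum within $\pm 10$ rows of a set point inside the tissue,
   and its phase is subtracted from the whole column in every frame. Rigid
   axial (bulk) motion contributes the same phase to every pixel of a
   column, so it cancels identically; what survives is motion *relative* to
   the reference depth.
2. **Temporal unwrapping.** After subtracting each pixel's first-frame
   value, the referenced phase series is unwrapped over the frames by
   adding multiples of $2\pi$ so that consecutive increments lie in
   $[-\pi, \pi]$.
3. **Regression.** The unwrapped series is regressed against the frame
   timestamps (ordinary least squares over all frames, not a first/last
   difference — the slope uses all the data and is insensitive to
   symmetric noise), and the slope converts to velocity as
   $v_r = \frac{d(\phi_P - \phi_{RP})}{d\tau}\,\frac{\lambda}{4\pi n}.$

With the corneal configuration (800 nm centre wavelength, 2 Hz frame rate,
$n = 1.37$, 10 frames) the window spans 5 s — quasi-instantaneous against
hours-long de-swelling — and aliasing caps the measurable velocity at
$v_{max} = \lambda f/4n \approx 292$ nm/s. A phase step of $\Delta\phi$ and
$\Delta\phi + 2\pi$ per interval are indistinguishable (this is tested,
not just documented); velocities beyond the cap fold back. The package
flags DVI images whose velocities approach the cap but deliberately does
**not** attempt spatial unwrapping from the reference pixel outward — a
plausible anti-aliasing strategy, but a different algorithm with its own
failure modes, and out of scope here.

Key parameters and defaults: `refractiveIndex` 1.37 (all reported
velocities are medium-corrected; configurable in `dviConfig()`),
`referenceHalfwidth` 10 px, smoothing boxcar 5 × 5 px. The set point is the
epithelial interface for corneas with an epithelium; for corneas without
one it is the midpoint between the anterior and posterior interfaces, which
halves the depth range to either interface and thus the worst-case aliasing
risk. The reference phase is taken from the single selected pixel, not an
average — variants that average several bright pixels would lower reference
noise but change the method; they are left as future config extensions.

Display smoothing is applied to the masked velocity image only, and never
before axial averaging: averaging correlated (pre-smoothed) pixels would
bias the profile's effective sample size, so the profile always consumes
raw pixels.

## 2. Graph-search segmentation

All downstream stages need the anterior and posterior corneal interfaces
per column. The segmentation is an iterative minimum-energy path search:

* **Energy maps** (`buildEnergy()`): the image is median-filtered (3 × 3),
  converted to either inverted amplitude (`max - value`; bright structures
  become valleys) or inverted vertical-gradient magnitude (strong
  horizontal edges become valleys), then boxcar-smoothed (3 × 3). Gradient
  *magnitude* is used so one energy serves both the dark-to-bright anterior
  and bright-to-dark posterior transitions.
* **Path search** (`minEnergyPath()`): dynamic programming over columns
  with a per-column vertical step bound (default 1 px; smooth corneal
  interfaces tolerate small steps, and the bound is configurable for steep
  scenes). Among equal-cost paths the lexicographically smallest row
  sequence from the left is returned — an arbitrary but deterministic
  tie-break that makes runs reproducible and testable. The implementation
  is verified against exhaustive path enumeration on small grids.
* **Iteration with blocking** (`iteratePaths()`): after each path, all
  pixels within ±10 rows are blocked and the search repeats — this is how
  multiple stacked interfaces (two vial walls, then tissue) are found in
  energy order.
* **The corneal pipeline** (`segmentCornea()`): restrict to a configured
  row range; find and block the container walls with the amplitude energy;
  find an approximate anterior profile (amplitude energy when a scattering
  epithelial band exists, gradient energy otherwise); shift each column so
  that profile becomes flat and discard margins; run a final
  gradient-energy search for the two interfaces; map back. Flattening
  matters because the step-bounded search cannot follow strongly curved
  interfaces cheaply, and the margins discard bright irrelevancies.

Filter sizes, blocking half-width, margins and the scene variant are
explicit configuration (`segmentationConfig()`) rather than tuned-in
constants, because their "lowest robust values" are scene-dependent. The
defaults here (median 3 × 3, boxcar 3 × 3, half-width 10) are the lowest
values robust across the synthetic vial scenes; on those scenes the 3 × 3
boxcar roughly halves the residual interface bias relative to 5 × 5
(+0.7 px versus −1.0 px in measured thickness). Manual review of "clearly
false paths" is replaced by an optional user block mask in the config —
the reproducible equivalent of a human blocking a stray reflection. As a
guard against confidently segmenting garbage, the pipeline additionally
requires the claimed cornea to be a scattering band: the mean amplitude
between the candidate interfaces must exceed twice the background mean
(walls excluded), otherwise a segmentation-failure error is raised.

Mapped-back paths satisfy a step bound of twice the search bound, because
the flattening shift and the flat-frame path each contribute one bound.

## 3. Thickness series

Per column, geometric thickness is
`(posterior_row - anterior_row) * pitch_air / n_G` with a constant
$n_G = 1.37$; hydration-dependent index variation is knowingly ignored
(it perturbs the absolute scale by ~1 %, uniformly). The series averages
the central 80 % of columns — edge columns clip the curved interfaces and
suffer mounting artefacts; the extent is recorded and configurable. Failed
time points become `NA` gaps rather than aborting the series, mirroring
how interrupted acquisitions are handled in practice, and irregular
sampling (1-minute early, 10-minute late) needs no special treatment.

## 4. The osmotic de-swelling model

The stroma is modelled as $N$ elements of equal **dry** thickness
$\delta = D_{dry}/N$ (default $N = 50$; doubling $N$ moves the endpoint
thickness by under 0.5 %). With unit densities for dry matter and water, an
element of hydration $H_i = M_W/M_D$ has wet thickness
$h_i = \delta(1 + H_i)$. CGS units are used throughout the model, matching
the units in which corneal transport constants are tabulated.

* **Swelling pressure.** The hydration–pressure relation of the swollen
  stroma is represented by a pluggable monotone-decreasing law, default
  $\Pi(H) = C\,H^{-\gamma}$ with $C = 2.41\times 10^6$ dyne/cm² and
  $\gamma = 2$. The literature's empirical relation is cited in transport
  studies but the published constant alone does not fix a functional form,
  so the package is explicit about the law it uses, records it in outputs,
  and keeps every acceptance-level property (conservation, equilibria,
  parameter recovery) law-agnostic.
* **Fluxes.** Element fluid pressure is $P_i = -\Pi(H_i)$. Interior Darcy
  flux between neighbours: $q = (k/\mu)(P_i - P_{i+1})/\Delta x$ with
  $\Delta x$ the distance between element centres. Posterior (endothelial)
  boundary: membrane flux $L(\pi_{ext} - \Pi(H_N))$, outward when the bath
  is hypertonic; $\pi_{ext} = \Pi(H_{eq})$ defines the de-swollen
  equilibrium. Anterior boundary: sealed by default (an intact epithelium
  passes negligible osmotic flow), with `membrane` and `open` variants.
  Solute (dextran) ingress is excluded, so the late re-swelling phase seen
  in long experiments is out of the model's scope by construction.
* **Integration.** Explicit Euler with a conservative diffusion-type
  stability bound on the step, $dt \le s\,\min(\Delta x\,\delta/2(k/\mu)|\Pi'|,\ \delta/2L|\Pi'|)$
  evaluated at the smallest reachable hydration; the scheme is the simplest
  whose convergence is directly testable (halving $dt$ moves the endpoint
  by $<0.1\%$). The inner loop is compiled; a pure-R reference stepper with
  identical arithmetic is kept and tested against it, and serves custom
  pressure laws. Water is conserved to machine precision by construction
  (the per-step hydration updates telescope to the boundary fluxes), and
  the trajectory records cumulative boundary outflow so conservation is
  checked, not assumed.
* **Velocity profiles.** Element boundary depths are accumulated from the
  anterior face, which is the zero-velocity reference — the same convention
  as DVI referenced at the epithelial interface. Velocities are finite
  differences of those depths between adjacent samples (central in the
  interior, one-sided at the ends), re-expressed as distance from the
  endothelial face in nm/s for comparison with measured axial profiles.

**Fitting** (`fitToDVI()`): the transport constants $(k/\mu, L, H_0,
H_{eq})$ are recovered from measured profiles at ≥3 times plus the
thickness at those times by a deterministic two-stage search — a coarse
grid over the bounds (log-spaced for the conductivities) followed by
Nelder-Mead refinement in $(\log k/\mu, \log L, H_0, H_{eq})$ with
out-of-bounds points penalised, the start nudged 5 % off grid corners
(a corner start otherwise straddles the penalty region and can collapse
the simplex), and one restart. Model profiles are linearly interpolated
onto the measurement distance grid; the thickness residual enters with a
fixed weight (10 (nm/s)²/µm², making a 1 µm thickness error comparable to
a ~3 nm/s profile error). An optional fitted time offset represents the
unknown interval between solution transfer and the first measurement; it
defaults to off, and the fitted model's start time and thickness are
reported as nuisance diagnostics. On noiseless synthetic profiles the fit
returns the generating constants to well under 1 %; with 5 % profile noise,
to well under 15 % across seeded replicates.

## 5. The synthetic phantoms

Raw complex recordings of de-swelling corneas are not publicly deposited,
so the package carries a first-class simulator whose outputs every stage is
tested against.

* **Scenes** (`makeCornealScene()`): a vial scene — two bright glass-wall
  reflections rendered ~3 px thick (a 1 px line would not survive the 3 × 3
  median filter that is part of the segmentation method, and real specular
  wall reflections are several pixels wide), a stroma of fully developed
  speckle (amplitude = magnitude of a unit-power complex Gaussian, i.e.
  Rayleigh), an optional brighter scattering epithelial band, specular
  reflection lines at the corneal interfaces (triangular sub-pixel kernel,
  amplitude 6× the stromal mean-square), and near-zero background. Truth
  paths are stored at sub-pixel precision, and interface rendering uses
  partial-pixel coverage so that the steepest-gradient locus coincides with
  the stated truth row — a phantom whose stated ground truth was not true
  of its own images would test nothing.
* **Deformation fields** (`makeDeformationField()`): uniform strain
  ($v = s(z - z_{ref})$), an exponential de-swelling front decaying from a
  boundary, velocities interpolated from a simulated model trajectory,
  rigid bulk motion, and static. All accept an additive bulk-motion term.
* **Rendering** (`renderFrameStack()`): frozen speckle amplitude, phase
  evolving exactly as $\phi_0 + (4\pi n_G/\lambda)\int v\,dt$ (trapezoidal
  in time), independent complex Gaussian noise per pixel per frame with
  $\sigma = 1/\mathrm{SNR}$ relative to the unit stromal power. Scatterer
  displacement over a 10-frame stack is far below one pixel for every
  velocity of interest (≤292 nm/s × 5 s ≪ 3.8 µm), so amplitude
  decorrelation is negligible and deliberately not modelled.

What the phantoms do **not** emulate: lateral motion, vial-wall dispersion
artefacts, folded-interface overlays, polarisation effects, depth-dependent
SNR, and the true (unpublished) SNR of any particular instrument — the
12 nm/s raw noise floor of the original system therefore cannot be
reproduced as a number, and all noise tests are parameterised by SNR with
the *hierarchy* raw > smoothed > axially-averaged and its ~$N^{-1/2}$
averaging law as the invariants. Passing tests demonstrate correctness of
the computational chain under these conditions, not instrument performance
on real tissue.

## 6. Numerical choices and degenerate inputs

* Phases live in $(-\pi, \pi]$; wrapping uses rounding to the nearest
  $2\pi$, so an exact $\pm\pi$ increment resolves to $+\pi$ (tested; the
  choice is invisible at any finite noise).
* Zero-amplitude pixels have no defined phase; the DVI validity mask
  excludes them. Real data never contains exact zeros, but noiseless
  phantom edges do.
* Boxcar filters shrink their window at image borders (no padding bias);
  the NA-aware variant used for masked velocity images renormalises by the
  valid-pixel count.
* The 3 × 3 median filter is a vectorised 19-exchange sorting network,
  verified against a per-pixel median oracle.
* Ties: reference-pixel selection and path search both break ties toward
  the smaller row; uniform-energy images thus return the top row, which is
  asserted, not accidental.
* Degenerate model inputs fail loudly: non-positive hydration in the
  pressure law, oversized Euler steps (negative hydration), fully blocked
  columns in the path search, empty reference windows, all-equal
  timestamps, and degenerate fit bounds each raise a specific error.

## 7. Study conditions used by the validation suite

The default acquisition geometry is 800 nm / $n_G$ 1.37 / 2 Hz /
5.2 µm-per-pixel axial pitch in air / 10 frames. Model defaults are the
fitted human-cornea set ($k/\mu = 10\times10^{-12}$ cm⁴/(s·dyne),
$L = 179\times10^{-12}$ cm³/(s·dyne), $H_0 = 7.6$, $H_{eq} = 2.44$,
$C = 2.41\times10^6$ dyne/cm², sealed anterior), with
$D_{dry} = 120\ \mu m$ chosen so the initial swollen thickness
$D_{dry}(1+H_0) \approx 1.03$ mm matches a storage-swollen cornea.
Validation problem sizes are chosen to exercise every code path at desk
scale: 200 × 60 px scenes for per-stage checks, the full 420 × 120 px scene
for segmentation accuracy (20 random scenes at SNR ≥ 5), fits on profiles
at 5, 10 and 25 model minutes, and closed-loop thickness runs at
acquisition times from 5 to 58 minutes — the first measurement follows the
~5-minute re-immersion interval of the transfer protocol, and with the
default constants the early-phase velocities exceed the 292 nm/s aliasing
cap until roughly 20 minutes, so DVI-bearing conditions start later than
thickness-only ones.

## 8. Known limitations

* The swelling-pressure law's functional form is a package choice; fitted
  constants are therefore comparable *within* this model, and against
  reference ranges, but not guaranteed to match constants fitted under a
  different law.
* The model is 1-D with uniform thickness: no peripheral-to-central flow,
  no biomechanical asymmetry between anterior and posterior stroma, no
  solute transport — hence no re-swelling phase.
* DVI is axial-only, like all single-axis phase methods; strain-rate
  imaging via spatial phase gradients and multi-axis compositing are out
  of scope.
* Aliased velocities fold back silently at the pixel level; the package
  warns at the image level when velocities approach the cap but cannot
  repair aliasing.
* Segmentation accuracy is validated on synthetic scenes; real B-scans
  with unusual mounting, strong artefacts or detached tissue will need the
  config's row ranges and block masks.
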