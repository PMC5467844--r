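---
title: "Multi-prior metal artifact reduction for fan-beam CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-prior metal artifact reduction for fan-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metal implants attenuate diagnostic X-rays so strongly that the detector
receives essentially no photons along rays through the metal. The affected
sinogram samples — the *metal trace* `T_M` — carry no usable information,
and reconstructing them as if they did produces the familiar bright/dark
streaks that can make CT slices unreadable around implants. Projection
completion methods treat the trace as missing data and re-estimate it from
its surroundings; `ctmar` implements three of them, together with the
simulation machinery needed to study them quantitatively:

* **LIN** — 1-D linear interpolation across every trace run, per view.
* **NMAR** — interpolation of the sinogram *normalized* by the forward
  projection of a prior image, then denormalization.
* The **multi-prior method** — the package's centrepiece: the pre-corrected
  image is partitioned into `N` intensity tiers by recursive active-contour
  segmentation, the tiers' forward projections form a sinogram basis
  `beta_j`, nonnegative coefficients `d_j` are fitted to the measured data
  outside the trace, and the trace is replaced by `sum_j d_j beta_j` plus a
  trace-interpolated copy of the residual `delta = p0 - sum_j d_j beta_j`.
  The correction is iterated, re-segmenting the improved image each round.

All corrections happen in sinogram space and share a hard contract: the
corrected sinogram equals the measurement bit-for-bit outside `T_M`.

## Segmentation model

The two-phase Chan–Vese energy drives all segmentation:

```
F(phi) = int (I - c1)^2 H(phi) + (I - c2)^2 (1 - H(phi)) + mu |D H(phi)|
```

with the smoothed Heaviside `H_eps(t) = (1 + (2/pi) atan(t/eps)) / 2`,
`eps` = 1 pixel, region means `c1`, `c2`, and contour-length weight `mu`.
`chan_vese()` alternates exact mean updates with backtracking gradient
descent on `phi`, so the energy is non-increasing across accepted steps by
construction.

Three numerical choices matter and are worth stating explicitly:

* **Initialization.** The level set starts from the ISODATA two-means
  threshold of the intensities, converted to a signed distance to the
  threshold mask. A geometry-only initialization (checkerboards of circles)
  collapses under the length term before the means separate, because the
  smoothed-Heaviside flow is local; starting at an intensity split lets the
  descent refine a sensible contour instead of having to create one.
* **Model comparison.** Gradient descent cannot remove a large unprofitable
  contour (the curvature force scales like 1/R). `chan_vese()` therefore
  compares the converged two-region solution against the one-region model:
  the split is kept only if its data-term improvement exceeds `mu` times
  the digital perimeter of the foreground. This single rule is what makes
  `mu` the *sensitivity* knob: low-contrast tiers and thin partial-volume
  shells do not pay for their perimeter and are rejected.
* **Intensity scale.** `mu = 0.1` is calibrated for images expressed in
  1/cm — the scale on which tissue tiers span roughly 0.2 to 0.6. Inside
  `rac_segment()` the energy is evaluated on `attenuation / 0.1`
  (1/mm to 1/cm); a per-image range normalization would destroy the
  absolute-contrast semantics that the recursion's stopping behaviour
  relies on.

`rac_segment()` applies the model recursively: record the foreground as the
next prior level, replace the background with the foreground's robust
minimum (the 10% quantile — equal to the minimum for clean
piecewise-constant data, but insensitive to the partial-volume ramp at
region borders and to noise outliers), and repeat until the contour
degenerates, the working image is constant to within 1% of the initial
range, or a cap of 10 levels is reached. `N` is therefore chosen by the
data: on the package's Shepp-Logan variant the recursion resolves object,
bright-tissue tier and bone (N = 3); on the four-tier abdomen phantom it
resolves N = 4.

Subregion *values* (used for NMAR priors and as the coefficient fit's
initial guess) are medians rather than means: the mean of a segmented
region is dragged toward the background by its partial-volume border ring,
while the median estimates the plateau value; for a homogeneous region the
two coincide.

## Metal segmentation

`segment_metal()` runs Chan–Vese on the reconstruction clipped to
`[0, 3] /mm` with the contour initialized in the metal intensity range,
then keeps connected components whose mean attenuation exceeds 0.3/mm
(several times cortical bone) and trims each component at half its median
value, because the reconstruction point-spread smears the extreme metal
edge into neighbouring pixels. On noiseless simulations the mask matches
the ground-truth inserts exactly; under severe photon starvation the
brightest blooming pixels adjacent to the implant are genuinely in the
metal intensity range and the mask dilates slightly — which only widens the
trace conservatively.

## The coefficient fit

`fit_coefficients()` minimizes

```
|| p0 - sum_j d_j beta_j ||_{T_M^c}  +  alpha || grad p0 - sum_j d_j grad beta_j ||_{dT_M}
```

over `d_j >= 0`, with Euclidean norms, `alpha = 0.1`, and the gradient
taken as outward one-sided finite differences along the detector-channel
axis at the trace-boundary samples (differences that would touch a trace
channel are dropped — corrupt data must not enter the fit). Nonnegativity
is enforced by optimizing `u = log d` with Nelder–Mead (relative tolerance
1e-10, `200 N` iterations, one restart from the best vertex). On a phantom
built exactly from the basis the fit recovers the true region attenuations
to machine precision.

One modelling point deserves emphasis: pixels under the segmented metal are
attributed to the *outermost* subregion when the basis is projected. The
rays through those pixels are exactly the rays being re-estimated, so a
hole in the basis there produces a systematic deficit that boundary
interpolation of the residual cannot see, let alone repair. With the
attribution, the multi-prior fill is several times more accurate than LIN
on ideal data; without it, several times worse.

The basis uses the *exclusive* tiers (set differences of the nested
foregrounds), so each `d_j` estimates a region's attenuation directly —
coefficients come out as interpretable tissue values (about 0.23, 0.39 and
0.62 1/cm for the Shepp-Logan variant) rather than cumulative increments.

## The outer loop and its stopping rule

`proposed_mar()` initializes with LIN, then loops: RAC partition →
basis → fit → trace replacement with residual compensation → FBP. The loop
stops when the residual norm over the trace complement falls below
`tau = 0.10` times its first-iteration value, when `max_outer` is reached,
or when the norm stops improving — operationalized as no 1% improvement
over the best value for three consecutive iterations, because with Poisson
noise the norm settles at the noise floor and oscillates there rather than
decreasing smoothly. The state of the best iteration is returned, with the
segmented metal pixels re-inserted from the uncorrected reconstruction (the
implant should remain visible in the displayed image). On noiseless data
the `tau` rule fires; on noisy data the floor-stagnation rule usually does.

## Simulation model

* **Geometry** — fan beam, flat equispaced detector: source–isocenter
  929.19 mm, detector–isocenter 525.24 mm, 1024 channels at 0.388 mm, 1080
  views over 360°, 512² image at 0.2 mm pixels. The package's *desk scale*
  keeps the full detector and field of view but uses 360 views and a 256²
  grid at 0.4 mm — chosen so a complete six-method comparison of three
  phantoms runs in minutes on one core.
* **Spectrum** — Kramers bremsstrahlung hardened by 8 mm Al-equivalent
  total filtration, 1 keV bins, normalized; at 120 kVp the mean energy is
  60.3 keV, typical of measured clinical spectra (the bare Kramers model
  lacks anode self-filtration). Any tabulated spectrum can be substituted.
* **Attenuation** — an ICRU-44-style mass-attenuation table (air, water,
  muscle, cortical bone, gold with its 80.7 keV K edge, aluminium),
  log–log interpolated and density-scaled; approximate to a percent or two
  and intended for simulation, not dosimetry. Phantom primitives may carry
  a density scale factor, the usual device for building tissue variants.
* **Noise** — per ray, the polychromatic transmitted intensity is
  Poisson-sampled with the open-beam mean at 10⁶ photons per detector cell
  and clamped to one photon before the log; rays through gold therefore
  saturate at `ln 10⁶ ≈ 13.8`, which reproduces realistic
  photon-starvation streaks.
* **FBP** — cosine weighting, Ram-Lak ramp with Hann apodization cut off
  at the reconstruction grid's Nyquist frequency (detector frequencies the
  grid cannot represent only alias into noise), distance-weighted
  backprojection. The forward projector is Joseph-style ray tracing with an
  exact adjoint.
* **Reference** — the metal-free phantom simulated noiselessly with the
  same polychromatic spectrum and reconstructed identically, so the
  reference carries the same beam-hardening signature and MSE measures
  artifact, not physics.

## Phantoms

Three study phantoms emulate increasing complexity: a Shepp-Logan variant
with a cortical-bone shell, a bright soft-tissue tier and two 4×4 mm gold
rectangles at (±15, −10) mm; a jaw-like phantom (soft oval, denser inner
tissue, an arc of bone "teeth" plus condyles, three 2 mm gold circles); and
a four-tier abdomen-like phantom (soft tissue, dense organ, trabecular and
cortical bone, two gold circles). Tier attenuations and areas are chosen so
the tiers are genuine segmentation levels — each tier's area × contrast²
exceeds `mu` × perimeter by a comfortable margin at study scale, which is
what a phantom with visually distinct tissue classes means in energy terms.
All coordinates live in `phantom_library()`; the phantoms are "-like"
approximations, and `read_phantom_tsv()` accepts externally supplied
phantom rasters as a substitute.

What the synthetic data does *not* emulate: scatter, detector lag and blur,
focal-spot size (the 17×17 sub-ray option exists but defaults off), 3-D
cone-beam effects, and anatomical texture — real tissue is not piecewise
constant. Passing tests therefore demonstrate correctness of the algorithms
under the stated acquisition model, not clinical performance.

## Evaluation

MSE is computed in HU² (conversion at the spectrum's mean energy) over all
non-metal pixels against the beam-hardening-bearing reference;
`roi_std()` provides the ROI standard deviation used for real scans. At
desk scale the absolute MSE is dominated by the common Poisson noise floor,
so *orderings* between methods are the meaningful quantity; on the complex
jaw phantom, where multiple bone objects generate strong beam hardening,
the multi-prior method's residual compensation gives it a clear margin over
NMAR, while on the simple Shepp-Logan variant the two nearly coincide —
the expected behaviour, since for a piecewise-constant object and
monochromatic beam the two are mathematically equivalent (the package
demonstrates < 1 HU RMSE agreement in that limit).

## Known limitations

* Region values under an implant are guessed as the outermost tier; an
  implant embedded in bone is modelled as displacing soft tissue, and only
  the residual-compensation step softens the resulting bias.
* The recursion cannot distinguish a genuine thin dense structure from a
  partial-volume shell when their energy signatures coincide at the
  configured `mu`.
* With extreme photon starvation the segmented metal mask dilates by about
  a pixel into blooming; the trace widens correspondingly.
* The 2-D fan-beam implementation treats each slice independently; no
  cone-beam geometry is provided.
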