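---
title: "Localized transfer-function shifts: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized transfer-function shifts: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfshift)
```

## The problem

Direct volume rendering (DVR) maps each sampled intensity through a 1D
RGBA transfer function (TF) and composites the samples along view rays
under an emission–absorption model. In two-photon stacks of cortex this
breaks down for exploration: dendrites, axon bundles and somata overlap in
depth, span a wide intensity range, and structures running under blood
vessels are locally attenuated. Raising the opacity of a dim intensity
band globally reveals the attenuated tube *and* every other voxel in that
band, burying it again.

`tfshift` implements local TF editing. The preset TF is immutable; an edit
adds a per-voxel offset Δ(x) to the intensity *before* the lookup, so that
selected voxels borrow the appearance of a reference structure while the
rest of the volume is untouched. Each edit is data — a reference point, a
set of brushed sphere centers, two scalars and a metric name — so a whole
interactive session is a replayable script (`run_session()`).

## The shift model

For an edit with reference **x**₀, stroke centers **x**_Ω, sensitivity α
and radius β:

$$\Delta(\mathbf{x}) = \bigl(I(\mathbf{x}_0) - I(\mathbf{x})\bigr)\;
  e^{-\alpha\, d_F(C(\mathbf{x}),\,C(\mathbf{x}_0))}\;
  \frac{1}{1 + e^{\,d_E(\mathbf{x},\,\Omega) - \beta}}$$

and rendering evaluates `TF_preset(I(x) + Δ(x))` with the argument clamped
to the intensity domain. The structure of the formula enforces three
conditions:

* **(A) identity** — if `I(x) = I(x₀)` then Δ(x) = 0 *exactly* (the
  difference is a multiplicative factor, so this holds in floating point,
  not just approximately), and the voxel's RGBA is unchanged.
* **(B) feature similarity** — voxels with `C(x) ≈ C(x₀)` get weight
  `exp(−α d_F) ≈ 1`, so inside the region they are shifted to the
  reference intensity and acquire its preset color/opacity.
* **(C) locality** — the logistic factor is 0.5 at distance β and decays
  like `e^{−(d_E−β)}`; beyond β + 20 it is below 10⁻⁸, which after an
  8-bit quantization of the rendered image is invisible. The tests verify
  that rays never approaching within β + 20 of any stroke center render
  identically to within 1/255 per channel.

Both weights lie in [0, 1], so `g = f_F · f_E ∈ [0, 1]` and
`|Δ| ≤ |I(x₀) − I(x)|` always; with `g = 1` the shifted lookup returns
`TF_preset(I(x₀))` and with `g = 0` it returns the unedited color. These
limits are asserted analytically per voxel in the test suite.

Multiple saved edits combine by voxelwise summation
(`combine_shift_fields()`), with clamping deferred to TF evaluation. This
keeps composition linear and order-independent, and each edit's locality
guarantees that non-overlapping regions do not interact beyond the
logistic tail. An empty edit list is rejected rather than producing a
zero field, because a field needs a grid to live on; a session with no
edits simply skips shift computation.

## Shape features

The feature vector is built from the Gaussian-scale Hessian of the
(median-filtered, normalized) volume. With eigenvalues sorted ascending by
signed value, λ₁ ≤ λ₂ ≤ λ₃:

* a bright tube axis has λ₁ ≈ λ₂ ≪ 0 and λ₃ ≈ 0, giving the
  linear-structure measure `λ_ratio = λ₂/λ₁ − λ₃/λ₁ ≈ 1`;
* a bright blob has three comparable negative eigenvalues, `λ_ratio ≈ 0`;
* structures darker than their surroundings have λ₁, λ₂ > 0 and are
  forced to 0 by the branch conditions, as is the degenerate case λ₁ = 0
  (the quotients are undefined there and the voxel carries no bright
  structure). Signed-value ordering (not magnitude ordering) is what makes
  these branch conditions meaningful.

The axis eigenvector **e**₃ (eigenvector of λ₃) is kept only where
λ₁ ≤ λ₂ ≤ 0 — the corrected **e**′₃ is exactly zero elsewhere, so
background and dark voxels never carry a spurious orientation. In the
orientation metric `d_F = 1 − |e′₃(x)·e′₃(x₀)|` a zero vector therefore
maps to the maximal dissimilarity 1: suppressed voxels can never be pulled
toward the reference appearance. The absolute value makes the metric
invariant to the arbitrary eigenvector sign, and `d_F ≤ 0.5` admits
exactly the axes within 60° of the reference — the working threshold for
separating crossing fiber families.

Derivatives are estimated by separable sampled-Gaussian kernels
(truncated at 4σ, replicate edges) that are discretely renormalized:
smoothing preserves constants, the first-derivative kernel is exact on
linear ramps, the second-derivative kernel is exact on quadratics. This
makes the analytic fixtures in the tests (quadratic ramps, Gaussian blobs
and cylinders) sharp rather than approximate. Derivatives are taken in
voxel units; anisotropic spacing affects only the spatial distance d_E.
The per-voxel symmetric 3×3 eigendecomposition runs through LAPACK
(RcppArmadillo) in a compiled loop.

## Metric context and tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `scale` | Gaussian derivative scale (voxels) | 1.0 | matches tube radii of ~2 voxels; exposed per call |
| median `radius` | denoising window (voxels) | 1 (3³ kernel) | smallest kernel that removes shot noise without eroding thin tubes |
| `alpha` | feature sensitivity (unitless) | per edit | 1 ≈ permissive, 10 ≈ selective, 100 ≈ near-binary |
| `beta` | region radius (x-voxel units) | per edit | 0.5 locality weight at β; useful range 6–20 |
| `channel_spec` | Mahalanobis/dot channels | `λ_ratio + e′₃` | the two shape descriptors; intensity available as an extra channel |
| `step` | ray sampling interval (voxels) | 0.5 | with opacity correction, halving it changes pixels < 2/255 |
| `alpha_th` | picking opacity-sum threshold | 0.3 | surface-biased but robust to a few semi-transparent samples |
| covariance ε | diagonal regularization | 10⁻⁶·tr(V)/n, doubled until invertible | deterministic, mask-free; handles collinear channels |

σ (for the λ_ratio metric) and the channel covariance V are estimated over
*all* voxels of the volume — a deterministic, mask-free choice; a
foreground mask would make the metrics depend on a segmentation the method
is supposed to avoid. d_E is computed as the minimum over stroke centers
of the Euclidean distance in voxel units, scaled per axis by
`spacing/spacing_x` — a brushed stroke is a swept union of spheres, and a
single center reduces to the plain pointer distance. Expressing β in
x-voxel units keeps the familiar parameter regimes (β = 6, 10, 20)
meaningful on anisotropic stacks.

Whether features should be computed on the raw or the denoised volume is
not dictated by the model; the pipeline computes them on the
median-filtered, normalized volume (the same field the shift reads
I from), which keeps Condition (A) exact end-to-end. The filter is 3D
(2D-per-slice filtering would denoise anisotropically and bias e′₃ toward
the slice plane). I(x₀) is read from that same volume, trilinearly
interpolated at fractional reference positions; feature values at x₀ use
the nearest voxel, since features are per-voxel quantities.

## Renderer and picking

The renderer is a CPU orthographic ray caster: one parallel ray per pixel
along the view direction, trilinear interpolation of both I and Δ at
fixed intervals, per-sample lookup through the shifted TF, opacity
correction `a' = 1 − (1 − a)^(step/ref_step)`, front-to-back compositing
with early termination at accumulated opacity 0.99, then the background.
Axis-aligned views place one pixel per voxel column by default, so image
pixel (i, j) is the column through voxels (i, j, ·). A GPU slice-based
scheme would produce the same integral; ray casting is simply the natural
CPU formulation of the same emission–absorption model.

Picking inverts the projection: from the clicked pixel the ray is marched
front to back at the renderer's step, and the *plain running sum* of
sample opacities (no compositing correction) is accumulated until it
reaches `alpha_th`; that sample, rounded to the nearest voxel, is
returned. The sum-of-opacities form is deliberately simple — it biases the
pick toward the front surface of the first sufficiently opaque structure,
which is the voxel a user pointing at a rendered structure means. Because
opacities are evaluated through the shifted TF, a structure visible only
by virtue of an edit is pickable, closing the interaction loop: pick →
edit → render → pick.

Degenerate inputs are handled explicitly: a constant volume cannot be
normalized (error); a reference with zero e′₃ under the orientation
metric yields d_F = 1 everywhere with a warning; a singular channel
covariance is regularized before inversion; rays that miss the volume
composite to the background; a pick that never reaches the threshold is a
miss, not an error.

## The phantom generator

`make_crossing_scene()` emulates the validation-relevant structure of a
two-photon stack: bright Gaussian-profile tubes (radius 2 voxels) in two
orientation families crisscrossing in the xy plane — by default along
(1, 1, 0) and (1, −1, 0), peaks 0.9 (family A) and 0.45 (family B, the
low-contrast target) — an axis-aligned shadow box in which intensities
are multiplied by 0.4 *before* noise (the attenuation under a blood
vessel), additive Gaussian noise of sd 0.02, clipping to [0, 1], and a
96³ default grid. Gaussian radial profiles stand in for PSF blur and keep
the Hessian well-posed; labels record the locally dominant tube (voxelwise
argmax, ties to the lower id) for ground-truth harnesses, and the seed is
stored in the scene. The two families are 90° apart, so the orientation
metric's 60° admission cone separates them with a wide margin; the
separation harness measures a misclassification rate well under 5% on
axis voxels.

What the phantom does **not** model: depth-dependent scattering and
excitation falloff, Poisson photon statistics, curved or branching
neurites, somata mixed into the same scene, and acquisition anisotropy.
Passing tests on these phantoms therefore validate the *mechanics* of the
method — feature correctness on ideal tubes, locality, identity,
monotonicity, metric separation — not its end-to-end performance on real
tissue, where feature scales and α must be chosen against noise and
curvature.

## Numerical choices

* Intensities are normalized to [0, 1] before features and shifts, making
  TF domains and Δ magnitudes comparable across inputs.
* Coordinates are 1-based voxel indices (fractional allowed), the native
  R convention; world position is `(index − 1) × spacing` µm. TIFF pages
  are the z axis.
* `exp(d_E − β)` may overflow to `Inf` for distant voxels; IEEE semantics
  then give a locality weight of exactly 0, which is the correct limit.
* The orientation sweep in the acceptance checks allows 10⁻⁹ slack at the
  60° boundary: `cos(60°)` is not exactly 0.5 in double precision.
* Volume I/O: NRRD (raw little-endian doubles, spacing in the header)
  round-trips bit-exactly and is the format used for persisted shift
  fields; TIFF stacks are written as 32-bit float pages. A minimal NRRD
  codec is included so that volumes, label maps and shift fields share
  one self-describing on-disk format.

## Problem sizes used in the checks

Unit fixtures are 5³–32³; the brute-force shift oracle runs on 16³ for
all four metrics; the study scene for locality, family separation and the
α/β parameter sweep is the 96³ default phantom (features computed once and
reused); the parameter sweep renders the 3 × 3 grid α ∈ {1, 10, 100} ×
β ∈ {1, 10, 20}. These sizes give every property room to fail while
keeping the full suite and the acceptance script fast on a single CPU.

## Known limitations

* Single-scale Hessian features: tubes much thicker or thinner than the
  chosen scale score lower on λ_ratio; there is no multi-scale maximum.
* The renderer is orthographic and unshaded by design; no perspective,
  lighting, or maximum-intensity mode.
* Picking uses the plain opacity sum, so `alpha_th` is not comparable to
  composited opacity values; it is a tunable with a deliberately simple
  meaning.
* Edits combine additively; many overlapping edits can overshoot the
  intended intensity (clamping at lookup bounds the damage but does not
  prevent it).
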