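# tfshift

Selective direct volume rendering of overlapping tubular structures in 3D
microscopy stacks by **localized transfer-function shifts**.

Two-photon stacks of cortex contain dendrites, axon bundles and somata that
overlap in depth and span a wide intensity range; structures passing under
blood vessels are additionally attenuated. A single global 1D transfer
function (TF) cannot show a dim tube without also flooding the image with
everything else at that intensity. `tfshift` implements a local editing
model instead: the preset TF is never modified — each voxel's *intensity*
is offset before the lookup, by an amount that depends on how similar the
voxel's shape features are to a user-chosen reference structure and on how
close the voxel is to a brushed region of interest.

## The model

For a reference point **x**₀ and brushed sphere centers **x**_Ω, the
per-voxel shift is

```
Δ(x) = (I(x₀) − I(x)) · exp(−α d_F(C(x), C(x₀))) / (1 + exp(d_E(x, Ω) − β))
```

and rendering evaluates `TF_preset(I(x) + Δ(x))`. The three factors encode
three design conditions:

* **Identity** — the factor `I(x₀) − I(x)` makes Δ vanish wherever a voxel
  already has the reference intensity, so the edit can never disturb what
  it is anchored to.
* **Feature selectivity** — `exp(−α d_F)` admits only voxels whose
  features match the reference; the sensitivity α sets how strict the
  match must be.
* **Locality** — the logistic term is ≈1 deep inside the brushed region Ω,
  0.5 at distance β from its centers, and negligible (< 10⁻⁸) beyond
  β + 20, so the edit cannot leak across the volume.

Features `C(x)` are Hessian-based shape descriptors computed at a Gaussian
scale: the eigenvalues λ₁ ≤ λ₂ ≤ λ₃ of the smoothed second-derivative
matrix give a linear-structure measure

```
λ_ratio = λ₂/λ₁ − λ₃/λ₁   (λ₁ ≤ λ₂ ≤ λ₃ ≤ 0;  λ₂/λ₁ if λ₃ > 0;  else 0)
```

that is ≈1 on the axis of a bright tube and ≈0 on blobs and background,
and a corrected axis eigenvector **e**′₃ (the λ₃ eigenvector, zeroed
wherever λ₂ > 0, i.e. where there is no bright structure). Four
dissimilarities d_F are available: orientation `1 − |e′₃(x)·e′₃(x₀)|`
(d_F ≤ 0.5 admits axes within 60° of the reference), the standardized
λ_ratio distance `|λ_ratio(x) − λ_ratio(x₀)|/σ`, the Mahalanobis distance
on a configurable channel vector, and an inner-product distance on
normalized channels.

The package also provides a CPU orthographic ray caster (front-to-back
emission–absorption compositing with opacity correction), 3D picking by
accumulated opacity along the view ray — evaluated through the *shifted*
TF, so structures revealed by an edit are clickable — and a seeded phantom
generator producing crossing-tube scenes with a vessel-shadowed
low-contrast region for validation.

## Worked example

```r
library(tfshift)

scene <- make_crossing_scene(shape = c(64, 64, 64), seed = 7)
vol   <- normalize_intensity(median_filter(scene$volume))
fv    <- build_feature_volume(vol, scale = 1)
print(fv)
#> feature_volume: 64 x 64 x 64 voxels, scale 1, channels [lambda_ratio, e3x, e3y, e3z], sigma(lambda_ratio) = 0.2373

# reference: an axis voxel of a dim family-B tube, outside the vessel shadow
av <- axis_voxels(scene, 6)
x0 <- av[!scene$shadow_mask[av], ][1, ]
ed <- edit_operation(x0, rbind(x0, x0 + c(4, -4, 0)),
                     alpha = 10, beta = 6, metric = "orientation")
sf <- compute_shift_field(vol, fv, ed)
print(sf)
#> shift_field: 64 x 64 x 64 voxels, 1 edit(s), range [-0.1107, 0.1557]

tf <- transfer_function(data.frame(intensity = c(0, 0.3, 0.45, 1),
                                   r = 1, g = 0.9, b = 0.6,
                                   a = c(0, 0, 0.6, 0.85)))
st   <- render_settings(c(0, 0, -1), background = c(0, 0, 0, 0))
base <- render_volume(vol, tf, settings = st)
edit <- render_volume(vol, tf, sf, st)
sum(apply(abs(edit - base) > 1/255, c(1, 2), any))
#> [1] 14            # only pixels near the brushed region changed

pk <- pick_voxel(vol, tf, sf, st, x_click = x0[1:2])
print(pk)
#> pick_result: hit at (35, 18, 21), sum(alpha) = 0.603 (threshold 0.300)
```

The shift field's positive values (up to 0.156) lift voxels of the brushed
tube toward the reference intensity; its small negative values dim brighter
crossing material inside the region. Only 14 of 4096 image columns change —
the edit is local. The pick marches the clicked ray front to back through
the shifted TF and returns the first sample whose running opacity sum
crosses the threshold; here it lands on the nearest visible structure in
that column (a crossing tube at z = 21 above the brushed one).

Scripted end-to-end sessions (`run_session()`, JSON configs) and a thin
CLI (`inst/cli/tfshift.R` with `phantom`, `features`, `shift`, `render`,
`pick`, `run` subcommands) wrap the same functions; see the methods
vignette (`vignettes/localized-tf-shift.Rmd`).

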