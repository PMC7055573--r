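---
title: "Adaptive auto-encoder learning for hyperspectral tumor detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive auto-encoder learning for hyperspectral tumor detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hyperspectral reflectance imaging records a full spectrum (hundreds of
narrow wavelength bands, here 450–950 nm) at every pixel of a tissue
surface. Tumor and healthy tissue differ subtly but consistently in their
reflectance spectra, so a per-pixel classifier over the spectral axis can
delineate a tumor — including margins that are irregular and visually
indistinct — without contrast agents. Two difficulties dominate in
practice: uneven surface illumination multiplies whole spectra by a smooth
spatially varying factor, and dark curvilinear structures such as blood
vessels imitate the absorption signature of tumor tissue. Both produce
structured misclassifications that a purely spectral model cannot avoid.

`adapthsi` implements a detection pipeline addressing exactly this setting:

1. **Reflectance calibration.** Raw counts are corrected voxel-wise with a
   white reference (100% reflectance) and a dark frame (shutter closed):
   `I = (raw − dark) / (white − dark)`.
2. **Deep feature learning.** A sparse auto-encoder with one sigmoid hidden
   layer learns a compressed representation of pixel spectra; the decoder
   is then removed and a two-class softmax head is stacked on the encoder
   to classify each pixel as tumor or healthy.
3. **Adaptive weight learning.** The initial detection on the training
   cubes defines per-pixel weights: correctly classified pixels keep
   weight 1, while (depending on the mode) false negatives receive the
   detection's sensitivity or false positives its specificity. Each
   training cube is multiplied pixel-wise by its weight map, and the whole
   network is retrained from scratch on the re-weighted cubes. Shrinking
   exactly the misclassified pixels makes them spectrally distinct from
   their class surroundings, so the retrained model concentrates capacity
   on the hard pixels.
4. **Post-processing.** The binary detection is refined by flood-filling
   enclosed holes and keeping the biggest connected component.

## The model in detail

With `X ∈ R^k` a pixel spectrum (k bands), the auto-encoder computes

    Y = f(w1 X + b1),   Z = f(w2 Y + b2),   f(p) = 1 / (1 + exp(−p)),

with `w1 ∈ R^{d×k}`, `w2 ∈ R^{k×d}`, `d < k`. The training loss combines
three terms:

    L = MSE(X, Z) + λ/2 (‖w1‖² + ‖w2‖²) + β Σ_j KL(ρ ‖ ρ̂_j),

where `ρ̂_j` is hidden unit j's mean activation over the batch and
`KL(ρ‖ρ̂) = ρ log(ρ/ρ̂) + (1−ρ) log((1−ρ)/(1−ρ̂))`. MSE is averaged over
all `n·k` matrix entries. Defaults are `λ = 1e-3`, `ρ = 0.05`, `β = 1`,
the long-standing sparse-auto-encoder convention (they are also the
defaults of the classic MATLAB implementation of this architecture). All
are exposed in the configuration.

Classification replaces the decoder by a softmax over two classes. Training
is two-stage: the head is fit on the frozen encoded features, then encoder
and head are fine-tuned jointly at a tenth of the head's learning rate.
The decision rule is `P(tumor) ≥ 0.5`, with ties classified tumor.

The adaptive weights are, for prediction `Pri` and truth `true` at pixel
`P_ij`,

    weight_se(P_ij) = 1 if Pri = true;  se(mask) if Pri = 0, true = 1
    weight_sp(P_ij) = 1 if Pri = true;  sp(mask) if Pri = 1, true = 0

and the update multiplies every band of `P_ij` by `weight(P_ij)`. The two
modes are mutually exclusive; for each training set both are evaluated by
retraining and the one with the higher mean training-set accuracy is kept
(ties go to the sensitivity mode, logged). Because weights never exceed 1,
reflectance stays in `[0, 1]` and no re-normalization is applied after the
update. Held-out cubes are never weighted — the weights require true
labels, which exist only for training data.

## Optimization and numerical choices

* **Optimizer.** Minibatch Adam (β₁ = 0.9, β₂ = 0.999), batch 256. The
  auto-encoder default learning rate is `1e-3`. The softmax head uses a
  larger default step (`3e-2`): the KL sparsity penalty compresses hidden
  activations to a scale of a few hundredths, and a head trained at the
  auto-encoder's rate moves too slowly to leave the majority-class optimum
  on imbalanced tumor fractions. Fine-tuning runs at a tenth of the head
  rate.
* **Best-iterate return.** The full-data loss is evaluated at every epoch
  boundary and the best parameters seen are returned, so the final loss
  never exceeds the initial one regardless of minibatch noise. A non-finite
  loss aborts with the epoch reported.
* **Clamping.** Mean activations inside the KL term are clamped to
  `[1e-7, 1 − 1e-7]`; clamped units contribute zero gradient.
* **Initialization.** Symmetric uniform weights scaled by `1/sqrt(fan-in)`,
  biases zero, all seeded. Every routine that consumes randomness takes an
  explicit seed, and the leave-one-out driver derives per-fold seeds from
  the run seed, so entire runs are bit-reproducible.
* **Calibration clipping.** Reflectance is clipped to `[0, 1]` by default:
  the sigmoid decoder can only produce values in `(0, 1)`, so unclipped
  specular highlights would be unreconstructable targets. A flag disables
  clipping. A voxel where `white = dark` is a hard error naming the voxel —
  a silent epsilon would hide acquisition faults.
* **Connectivity.** Foreground components use 8-connectivity, background
  (hole) reachability 4-connectivity — the standard dual pairing that
  avoids counting a diagonal line as both connected and hole-tight. Equal
  sized components tie-break to the one whose first pixel in row-major
  order comes first; an empty detection refines to empty with a warning
  rather than an error.
* **Tuning protocol.** The hidden dimension is chosen per training set by
  resubstitution: train at each candidate `d`, score mean per-sample
  detection accuracy on the same training samples, take the argmax (ties
  to the smaller, cheaper `d`). The mode choice uses the same protocol.
  Resubstitution is the deliberate default; the held-out sample of each
  fold never influences tuning, weighting, or training.
* **Mode-selection scoring.** The adaptively retrained classifier is scored
  on the *original* (unweighted) training cubes, because that is how the
  model is deployed on test data.

## The synthetic phantom generator

No animal hyperspectral dataset is distributed with the package, so every
claim is validated on synthetic phantoms whose ground truth is known by
construction. A phantom emulates the statistical structure the method
assumes:

* **Two spectral classes.** Smooth mean reflectance curves in `[0, 1]`; the
  tumor curve is the normal curve plus `separation` times a smooth bump, so
  class contrast is tunable and zero separation is an exact negative
  control.
* **Tumor geometry.** One 4-connected, hole-free region (ellipse or
  noise-distorted blob) covering ~`tumor_fraction` of the image, with
  seeded position, orientation and eccentricity.
* **Uneven illumination.** A low-order smooth multiplicative field (plane +
  one broad bump) shared across bands, peak-to-peak `illumination_amplitude`.
* **Vessel confounders.** Poisson-many random-walk polylines dilated to
  1–3 px, darkening spectra by a factor 0.5 — the structures that drive
  false positives.
* **Indistinct margins.** Within `margin_px` of the tumor boundary the
  class means are blended linearly by signed distance, while labels stay
  crisp — the label noise regime the adaptive step targets.
* **Pixel noise.** I.i.d. Gaussian per band, `noise_sd`.

Defaults (64×64 px, 64 bands, fraction 0.2, separation 0.15, noise 0.03,
illumination 0.2, 3 expected vessels, 2 px margins) describe a
confounder-rich but learnable condition; a cohort (default 12 samples,
mirroring a 12-animal study with leave-one-out evaluation) shares one pair
of class curves — the tissue classes — while geometry, illumination,
vessels and noise vary per sample. 64 bands rather than the full 251 keeps
desk runs fast; 251 is available by configuration.

The phantoms are statistical, not physical: there is no tissue-optics
(absorption/scattering) model, no spatial correlation in the noise, no
sensor model, and the illumination field is low-order. Passing tests
therefore demonstrate that the implementation realizes the method and that
the adaptive mechanism behaves as designed under the assumed structure —
not that any particular accuracy would be achieved on real animal data.

## Problem sizes used by the shipped experiments

The package's own cohort experiments (`desk_config()`, used by the test
suite and by `scripts/acceptance.R`) run the full 12-fold leave-one-out
pipeline at 64×64×64 with a two-point hidden-dimension grid {20, 35}, 800
training pixels sampled per cube, and epoch budgets 30 (auto-encoder) /
150 (head) / 40 (fine-tune). These sizes were chosen once as a desk-scale
protocol that keeps a full run in the minutes range on one CPU; the
package defaults (`run_config()`) keep the conventional 20–60 step-5 grid
and larger budgets for fidelity runs. The classifier sanity checks use a
separation-0.3, confounder-free phantom (where held-out pixel accuracy
above 99% is expected from linear separability) and a separation-0
phantom as the chance-level negative control.

## Known limitations

* The method is strictly per-pixel spectral; no convolutional or other
  spatial context enters the classifier (post-processing is the only
  spatial step). Baseline segmentation networks are out of scope.
* One adaptive round is the default and the tested regime; iterating the
  re-weighting to convergence is exposed (`adaptive_rounds`) but not
  characterized.
* Tuning by resubstitution can overstate training-set accuracy; it is kept
  because it is the protocol the pipeline defines, and the held-out
  evaluation is unaffected.
* The ENVI reader supports the BSQ/float32 dialect the package writes, not
  vendor-specific raw formats; masks are assumed pre-aligned to cubes.
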