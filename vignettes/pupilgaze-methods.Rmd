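---
title: "pupilgaze: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pupilgaze: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pupilgaze` implements the software half of a head-mounted eye tracker: from
a near-infrared eye image to a pupil ellipse, and from calibrated pupil
centers to a gaze point on a screen or scene image. This vignette explains
the models the package implements, the assumptions they rest on, and the
choices we made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The segmentation network

The pupil detector is a compact U-shaped encoder-decoder
(`net_config()`, `net_init()`, `segnet_forward()`, `train_segnet()`):

* **Encoder.** Five down blocks of four 3×3 convolutions each, every
  convolution followed by batch normalization and LeakyReLU (negative slope
  0.01). A 2×2 average pooling follows each of the first four blocks, so the
  fifth block — the bottleneck — sits at 1/16 of the input resolution. This
  is why input dimensions must be divisible by 16 (and at least 32 px).
* **Eye-closure head.** A global average pool of the bottleneck feeds one
  linear unit with a sigmoid, producing the closure probability
  `Pclose`. The head sees only the bottleneck; whether skip features should
  also contribute is undocumented in the source material, and the bottleneck
  alone is the minimal reading.
* **Gating.** Before upsampling, the decoder is switched by
  `G = Heaviside(1 − Pclose − ε)`. We adopt `Heaviside(0) = 1`: at the exact
  boundary the decoder still runs, favoring a segmentation over a refusal.
  `ε` defaults to 0.01, i.e. the decoder is skipped only when the network is
  ≥ 99% sure the eye is closed. A gated-off forward pass returns the
  all-zero probability map as an explicit sentinel.
* **Decoder.** Four up blocks; each upsamples ×2 with CARAFE, concatenates
  the skip connection from the matching encoder stage, and applies four
  convolutions (BN + LeakyReLU). A final 1×1 convolution and sigmoid yield a
  per-pixel pupil probability at input resolution.

### CARAFE upsampling

Content-aware reassembly of features replaces bilinear/deconvolution
upsampling. For each target location `q = (u, v)` of the ×`r` output, the
source location is `p = (floor(u/r), floor(v/r))` (we fix plain division to
floor division, since locations are integer indices). A kernel predictor —
one 3×3 convolution producing `r²m²` channels, pixel-shuffled to the output
grid — turns the content around `p` into an `m×m` kernel `K_q`, normalized
by a softmax over its `m²` entries so every kernel is a convex combination.
The output value is the `K_q`-weighted sum of the `m×m` neighborhood of `p`,
shared across channels, with zero padding at borders. Defaults: `m = 5`,
`r = 2` (fixed — four ×2 up blocks must undo four 2×2 poolings). The
predictor is zero-initialized, so training starts from uniform
neighborhood-averaging kernels. `carafe_reassemble()` is verified against an
independent brute-force triple loop in the test suite.

### Loss and training

Training minimizes `λ₁·Dice + λ₂·BCE` where Dice scores the pupil map and
BCE the scalar closure label. We set `λ₁ = 1, λ₂ = 0.5` (values are not
documented in the source material; segmentation is the harder, primary
task). The Dice loss uses the plain formula except in the all-background
degenerate case (both sums zero), which is defined as loss 0 via an additive
smoothing constant of 1; BCE clips probabilities to `[1e−7, 1 − 1e−7]`.

The optimizer is Adam with learning rate 0.001, decay rates 0.9/0.999 and
batch size 8 — the standard recipe for this model family. During training
the gate is **teacher-forced** from the ground-truth closure label: the
decoder and the Dice term run on open-eye frames only, so the decoder learns
from every open frame even while the closure head is still untrained; closed
frames contribute only the closure term. Inference gates on the predicted
`Pclose`. (Whether gating was applied at training time in the original
system is undocumented; teacher forcing is the choice that keeps both
branches learnable.)

All layers, the full backward pass, and Adam are implemented in the package
(R orchestration, Rcpp/RcppArmadillo im2col convolutions, pooling and CARAFE
kernels), because no deep-learning framework exists in the target R
environment. The analytic gradients are checked against numerical
differentiation end-to-end in `test-segnet.R`.

### Channel widths and the parameter budget

Channel widths are undocumented in the source material, which only states a
~1.2 MB model. The default (`base_channels = 8`, multipliers 1/2/2/4/4)
gives ≈ 252k parameters ≈ 1.0 MB at 4 bytes each, verified by
`net_parameter_count()`. The output bias is initialized to
`logit(0.05)` — the pupil covers only a few percent of a frame, and starting
at the class prior speeds Dice convergence on an imbalanced task. The
training smoke test uses `base_channels = 4`, a scaled-down width chosen so
30 epochs on 200 frames fit a single-CPU minute budget; at the fixed 0.001
learning rate and 30-epoch budget, wider configurations also converge
noticeably more slowly on this small corpus. The smoke run is a stand-in
for, not a reproduction of, full-resolution benchmark training.

## 2. Pupil geometry

`extract_pupil()` thresholds the probability map (default 0.5), keeps the
largest 8-connected component, and measures the pupil from
probability-weighted image moments: the center is the weighted centroid and
the ellipse semi-axes/orientation come from the eigendecomposition of the
second-order central moment matrix (for a solid ellipse the principal
moments are `a²/4`, `b²/4`). Moments need no iterative boundary fit and
degrade gracefully on small masks; components under 10 px yield
`valid = FALSE` rather than an error. "Two-axis rotational attitude" has no
operational definition in the source material, so the package reports the
raw ellipse parameters (orientation, axis ratio) as its stated proxy, and
the pupil diameter as the major-axis length `2a`.

## 3. Gaze mapping

Calibration fits bivariate polynomials
`u = A₀ + A₁x + A₂y + A₃x² + A₄xy + A₅y²` (likewise `v` with `B`), with
coefficient count `m = 1 + Σᵢ(1+i)` — 3 for first order, 6 for second. With
exactly `m` points the system is solved directly; with more, in the
least-squares sense via QR — the written `M⁻¹` only exists for square
systems, and least squares is precisely the stated mean-square-deviation
criterion. Rank-deficient designs are rejected with an explicit error.

Two geometric facts are worth recording:

* Six points determine the quadratic only **in general position**. The
  "corners plus vertical-midline pair" layout one might sketch first is
  conic-degenerate (design-matrix rank 5); `calibration_targets()` therefore
  uses corners + center + mid-top.
* Binocular fusion is undocumented in the source material; the package's
  position is per-eye models with averaged predictions, though the shipped
  pipeline exercises a single eye.

## 4. Metrics

* `five_pixel_rate()`: fraction of detections with center error strictly
  below 5 px (an error of exactly 5 px counts as incorrect).
* `precision()`: pooled `ΣTP / (ΣTP + ΣFP)`. The source formula is labelled
  "accuracy" but is the confusion-matrix precision; the formula is preserved
  exactly. Recall/F1 need a negative-class definition that the source never
  supplies, so the pipeline computes precision only, under the documented
  convention *TP = detection attempted and correct, FP = attempted and
  wrong*; frames where detection was not attempted enter no count.
* `rmse()`: scalar RMSE, or Euclidean-residual RMSE for 2-D points (so a 2 px
  jitter on each coordinate appears as ≈ √2·2 px).
* `angular_error()`: `acos` of the clipped cosine, in degrees, as eye-tracker
  accuracy is conventionally quoted; `gaze_angles_from_screen()` supplies the
  screen-to-vector geometry assuming the eye on the screen-center normal at
  the configured viewing distance (1 m default).
* `cross_validate()`: seeded k-fold assignment, each fold held out once,
  mean ± sd of the per-fold screen-space RMSE.

## 5. The synthetic world

`generate_eye_frame()` emulates what head-mounted dark-pupil recordings look
like, not how they are formed: a dark pupil ellipse (intensity 0.05–0.2)
inside a darker-than-skin iris disc (0.3–0.6) on a bright sclera/skin field
(0.5–0.9), corneal glints as saturated discs, an eyelid band, a linear
illumination gradient, and additive Gaussian noise clipped to `[0, 1]`.
Contrast values are ours — the source only establishes dark-pupil imaging —
and were chosen once for robust contrast. Defaults target the native 640×480
eye-camera resolution; tests use 64×64.

Ground truth is exact by construction: the ellipse mask is rasterized (pixel
centers at integer 0-based coordinates, x along columns) *before* any
nuisance rendering, so glints, occlusion and noise can never corrupt the
annotation. A frame is labelled closed when the eyelid covers ≥ 90% of the
pupil ellipse — "closed" has no definition in the source material — and open
frames keep the full (un-occluded) ellipse as their mask. Blink rate and
pupil-size distribution are unreported for the original recordings; the
defaults (10% closed, semi-major axis 20–60 px at full resolution) are our
choices, exposed in `synth_eye_config()`.

`generate_gaze_session()` samples pupil vectors uniformly over a
pupil-motion box, maps them through a generating polynomial
(`default_mapping_model()`: near-identity onto a 640×480 scene, mild
quadratic distortion, roughly unit Jacobian so pixel noise has pixel-scale
consequences), then jitters the *pupil vectors* with Gaussian noise —
emulating detection jitter, the dominant error source.

What a green test does **not** establish: photorealism (no 3-D eyeball, no
refraction, no texture), temporal dynamics (no saccades, no motion blur),
real eyelash/mascara structure, or transfer to LPW/ExCuSe-class recordings.
The trained smoke criterion (held-out Dice ≥ 0.8, 5-px rate ≥ 0.9 after 30
epochs on 200 synthetic frames) demonstrates that the architecture, losses
and optimizer learn this world end-to-end on one CPU — nothing more.

## 6. Reproducibility and the oracle mode

Every random draw routes through a private, restorable RNG stream keyed by
`(seed, stream)` sub-seeds (exact double arithmetic below 2³¹), so identical
configurations and seeds give bit-identical frames, splits, sessions and
reports, and library code never disturbs the caller's RNG.

`cmd_pipeline(oracle = TRUE)` bypasses the network entirely: detection reads
the ground-truth masks and calibration consumes exact annotation centers.
With zero session noise this isolates the geometry/calibration/metrics path,
whose end-to-end error is then pure floating point (RMSE below 1e−6 px) —
the oracle acceptance criterion. Pupil centers recovered from *rasterized*
masks carry ~0.1 px quantization, which is why the oracle gaze strand uses
annotation centers, while the 5-px detection rate is still measured on
mask-extracted centers.

## 7. Known limitations

* The environment offers no PNG codec or YAML parser in R, so images travel
  as plain-text PGM (P2) and configs as JSON; interfaces are otherwise as
  designed.
* Pure-CPU training: minutes for the 64×64 smoke world, impractical for
  640×480 corpora. The implementation is faithful, not fast.
* The eye-closure gate only engages when `Pclose ≥ 1 − ε`; with the default
  ε = 0.01 an under-confident closure head will leave the decoder running on
  blinks (they are then caught by the `valid = FALSE` path of
  `extract_pupil()`).
* Orientation of near-circular pupils is unidentifiable; the orientation
  recovery guarantee is stated (and tested) only for axis ratios ≥ 1.2.
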