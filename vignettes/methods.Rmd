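---
title: "Simulating developmental visual curricula with time-limited plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating developmental visual curricula with time-limited plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(blurriculum)
```

## The model

Human vision begins under degraded conditions — low acuity and poor color
sensitivity — while neuronal plasticity is at its peak, and both input
fidelity and plasticity change over development. `blurriculum` casts this as
a factorial training experiment on a small convolutional classifier:

* **Stimulus trajectory (regimen).** Training inputs are either
  full-fidelity or degraded (Gaussian blur with reference sigma 4 for the
  *acuity* domain, grayscale conversion for the *color* domain), ordered
  over epochs as F2F (always full), D2D (always degraded), D2F (degraded
  first half, full second half — the developmentally inspired order) or F2D
  (the inverse), plus partial-degraded and gradual-blur variants
  (`make_regimen()`).
* **Plasticity trajectory (learning-rate schedule).** The SGD step size
  stands in for plasticity: three constant rates (0.01, 0.001, 0.0001),
  three midway step decreases (0.01→0.001, 0.01→0.0001, 0.001→0.0001, all
  switching after the scaled midpoint), a five-block gradual decrease
  (0.01, 0.0075, 0.005, 0.0025, 0.001), and a reduce-on-plateau rule
  (factor 0.5, patience 5, min-delta 0, cooldown 0, floor 0)
  (`make_lr_schedule()`). Decreasing schedules are compared against the
  constant schedule sharing their initial value (or, in a control analysis,
  their final value): `matched_pairs()`.

The network (`arch_config()`) is a deliberately small conv→fc classifier —
by default three convolutional layers of 32, 64 and 64 filters (5×5 then
3×3 kernels, ReLU, 2×2 max pooling) and one hidden fully-connected layer of
128 units — trained with SGD, Nesterov momentum 0.9 and restricted
augmentation (random crop at a ≈ 227/256 crop ratio, random horizontal
flip, rescale to [−1, 1]), minimizing categorical cross-entropy. The first
layer is small enough to visualize filter-by-filter, which the
representational analyses require. Where the large-scale reference setting
uses 100 epochs with switches after epoch 50, all switch points here scale
proportionally with the configured run length, rounded to the nearest
epoch; "after epoch *k*" always means that epochs ≤ *k* keep the old value.

## The synthetic image sets

Training a network on a natural-image corpus is out of reach at desk scale,
so `generate_dataset()` builds procedural class-labeled image sets in which
class identity is carried **redundantly by two cue families**, each
selectively removed by one degradation:

* a **chromatic cue** — every class has a hue center, centers equally
  spaced on the hue circle; grayscale conversion removes this cue entirely;
* a **fine spatial-frequency cue** — every class textures its shape with
  band-pass filtered noise in a class-specific band (default centers 0.28
  to 0.48 cycles/pixel, above the reference blur's pass band); Gaussian
  blur at the reference severity suppresses these bands.

Two further design choices keep both degradations *consequential* for the
classifier rather than merely present in the pixels:

* **Hue is informative but noisy.** Each image's hue is jittered around
  its class center (default SD 18° against 36° spacing for ten classes). If
  every class had a unique deterministic hue, color would be a blur-proof
  shortcut and blurring would remove nothing the classifier needs; with
  jitter, hue narrows the class down without identifying it, as color does
  for natural categories.
* **Shape is ambiguous.** The default recycles five procedural shape
  families across ten classes, so shape — which survives both degradations
  — cannot solve the task alone.

Additive Gaussian pixel noise (SD 0.02, clipped to [0, 1]) discourages
pixel-level memorization. `cue_diagnostics()` verifies on any generated set
that class mean hues and texture-band centroids are separated, and that
grayscale conversion collapses the chromatic separation while leaving the
(luminance-borne) texture separation intact, and conversely for blur.

What the generator does **not** emulate: natural image statistics (1/f
spectra, clutter, occlusion), category hierarchies, within-class viewpoint
and identity variation, or any face-specific structure. Passing the
directional tests below shows that the *mechanisms* — shortcut reliance on
vulnerable cues, catastrophic forgetting of early representations, and
their protection by declining learning rates — operate in this simplified
world; it does not certify effect sizes on natural images.

## Degradation operators

* `gaussian_blur()` states sigma at a 256-pixel reference width and scales
  it by `width / 256`, so nominal sigma 4 removes the same fraction of
  image detail at any resolution. The kernel is truncated at 4σ with
  symmetric-reflection boundaries; all math is floating point with clipping
  to [0, 1] only at operator exit. Blur is applied to the full-resolution
  image before cropping, mimicking degraded optics acting on the whole
  stimulus.
* `to_grayscale()` uses ITU-R BT.601 luminance (0.299, 0.587, 0.114) — the
  common image-library default — replicated into three channels so tensor
  shapes are constant across regimens; it returns already-achromatic input
  unchanged, making idempotence exact.
* `hue_rotate()` shifts hue in a floating-point HSV decomposition,
  preserving saturation and value; it is the test-time probe for reliance
  on specific chromatic values (`hue_sweep()`, default 0–180° in 30°
  steps; the sweep grid is configurable since no canonical grid exists).

## Representational metrics

The receptive-field tuning metrics are this package's own declared
definitions (standard, scale-invariant choices):

* `color_tuning_score()`: the fraction of a first-layer filter's energy
  orthogonal to the achromatic axis (1,1,1)/√3 — 0 for grayscale-equivalent
  filters, 1 for pure color-opponent ones.
* `sf_centroid()`: the power-weighted mean radial frequency of the
  filter's achromatic component over non-DC Fourier bins, in cycles/pixel.

Weight dynamics use the mean absolute elementwise weight change and the
Pearson correlation of a layer's flattened kernel weights between adjacent
epoch checkpoints (biases excluded; correlation deliberately disregards
changes in absolute filter strength). A layer counts as *stabilized* at the
first epoch its adjacent-epoch correlation reaches 0.99 — a reporting
convention, not an estimated quantity. Filters of two runs are paired by
index under a shared initialization seed, the only reproducible pairing
that needs no assignment solving.

## Numerical and reproducibility choices

All randomness of a run — initialization, shuffling, crops, flips — flows
from one `train_config()` seed through R's RNG stream; the C++ training
kernels contain no randomness, so identical configurations reproduce runs
bitwise. The batch arithmetic inside the convolution/backprop kernels runs
in single precision (it is gemm-dominated); weights, updates and all
analysis metrics are double precision. Nesterov momentum uses the
`v ← μv + g`, `w ← w − lr(g + μv)` form, under which a zero learning rate
leaves weights bitwise unchanged. Prediction ties break toward the lowest
class index, so a constant-output model scores exactly chance on a balanced
set. No weight decay, dropout or warm-up is used — the training recipe is
deliberately restricted to SGD + momentum + light augmentation.

## Desk profile: problem sizes

The replication suite and `scripts/acceptance.R` use a fixed compact
configuration, `desk_profile()`: 10 classes × (60 train + 20 test) images
at 48×48 pixels, the default architecture on 40-pixel crops, 20 epochs
(switches after epoch 10), batch 64, three run seeds. These sizes were
chosen once so that the full two-domain grid — four regimens × matched
schedules × three seeds — trains on a single CPU in minutes while both cue
families remain informative; they are the package's stated study
conditions, and the replication suite checks directions (not effect
sizes):

* F2F accuracy is higher on full than degraded test images; D2D shows the
  opposite pattern (both domains);
* D2F's mean of full and degraded accuracy is at least F2D's;
* for D2F, the decreasing schedule (dec1) preserves degraded-input
  accuracy at least as well as its matched constant schedule (const1);
* in the color domain, most matched first-layer filter pairs fall below
  the diagonal of the color-score scatter; adjacent-epoch weight
  correlations rise after the rate drop; the first conv layer stabilizes
  no later than the last fully-connected layer.

Two of these directions reverse at desk scale, and the suite reports them
as failures rather than hiding them. In the color domain D2F (under the
constant baseline) falls below F2D on the combined score: desk-scale
catastrophic forgetting is strong enough that D2F loses most degraded
competence in phase 2, while F2D's full-fidelity knowledge largely
survives its degraded phase — the forgetting asymmetry overwhelms the
training-order benefit the large-scale setting shows. In the acuity domain
the dec1 − const1 delta on blurred tests is slightly negative: blur at the
scaled severity leaves clear-trained features largely usable (F2F retains
most accuracy on blurred tests), so the constant schedule's extra
phase-2 learning helps blurred classification more than forgetting hurts
it, and there is nothing blur-specific for the decreasing rate to protect.
Both are properties of the compact task, consistent with the reference
setting's observation that acuity-domain object-classification effects are
modest even at full scale.

The plateau schedule monitors full-fidelity test accuracy by default
(configurable): the monitored quantity is not canonical, and accuracy is
the natural "performance plateau" reading. Top-1 accuracy is used
throughout — the simplest reading of "classification performance".
Accuracies are fractions internally; report tables convert to percent.

## Known limitations

Effect sizes here are not comparable to large-scale results: the task is
far easier (ceiling effects compress differences), the network far smaller,
and the cue structure engineered. The acuity domain is intrinsically the
weaker analogue — blur leaves the (noisy) chromatic cue untouched, exactly
as blur leaves color available in natural images, so acuity-domain
orderings replicate with smaller margins than color-domain ones. Mixed or
interleaved-fidelity regimens, ResNet-scale architectures and face-specific
comparisons are out of scope.

## A worked example

```{r example}
library(blurriculum)

prof <- desk_profile(seeds = 1)
sets <- generate_dataset(prof$spec)
cue_diagnostics(sets$train)

run_dec <- train(prof$arch, sets$train, sets$test,
                 make_regimen("D2F", prof$epochs, degraded = "grayscale"),
                 make_lr_schedule("dec1", prof$epochs),
                 train_config(epochs = prof$epochs, seed = 1,
                              batch_size = prof$batch_size))
glance(run_dec)
evaluate(run_dec, sets$test, degradation("grayscale"))

run_con <- train(prof$arch, sets$train, sets$test,
                 make_regimen("D2F", prof$epochs, degraded = "grayscale"),
                 make_lr_schedule("const1", prof$epochs),
                 train_config(epochs = prof$epochs, seed = 1,
                              batch_size = prof$batch_size))
sc <- rf_scatter(run_dec, run_con, metric = "color")
attr(sc, "count_below") / attr(sc, "total")
plot_rf_scatter(sc)
autoplot(dynamics_profile(run_dec))
```
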