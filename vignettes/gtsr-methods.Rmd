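---
title: "Methods: model, objective, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, objective, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gtsr)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic data does and does not
emulate, the numerical choices, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Problem and model

Super-resolution inverts a known degradation, here bicubic downsampling
by an integer factor `s` (default 8). The inverse is one-to-many; the
package's premise is that a medical-image SR system must be judged not
only by resemblance to the ground truth (PSNR/SSIM) but by *consistency
with the observation it started from* — re-degrading the output must
reproduce the input. The architecture and objective are chosen around
that premise.

**Generator.** A pre-upsampling U-Net: the LR input is bicubically
interpolated to the HR grid, then a resolution-preserving encoder–decoder
with skip connections predicts a residual, and the output is
`clamp01(upsampled + residual)`. The bottleneck feature is flattened into
local tokens (3×3 convolution, row-major), `K` learnable global tokens
are prepended, and `T` residual multi-head self-attention layers
`Z ← Z + MSA(Z)` mix local and global context before the tokens are
reshaped back. Taken literally, the attention block has *no* layer
normalization and no feed-forward sublayer — the residual alone carries
the tokens — which yields a useful exact property: zeroing the output
projections `W_O` makes the whole stack a tokenize/detokenize round trip,
which the tests assert.

**Discriminator.** A VGG-style stack of [3×3 conv, 3×3 stride-2 conv]
blocks with LeakyReLU(0.2), channels doubling and capped (32…256 at the
defaults), global average pooling, and an affine map to one unbounded
scalar. No batch normalization (the usual hinge-GAN convention) and no
sigmoid, since the hinge loss operates on raw scores. At the defaults its
parameter count is well under the generator's (asserted as a unit test).

**Objective.** Hinge discriminator loss; generator loss
`L_G = L_adv + λ·L_PSNR` with `λ = 0.1`, where `L_PSNR` is the negative
batch-mean PSNR computed with peak value `M = 255` and an MSE floor
`ε = 1e−4`. Three loss modes (`hybrid`, `psnr_only`, `adv_only`) expose
the ablation variants as configuration.

## 2. Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `scale_factor` | 8 | degradation factor; 2048² → 256² |
| `scales` | 4 | U-Net down/up stages; bottleneck at 1/16 resolution |
| `base_channels` | 32 | doubling, capped at 8× → 32-64-128-256-256 plan |
| `token_dim` (d) | 256 | bottleneck token width; d_m = 64 with 4 heads |
| `heads` (M) | 4 | attention heads |
| `layers` (T) | 4 | residual MSA layers |
| `global_tokens` (K) | 8 | small relative to N; purely contextual |
| `lambda_psnr` | 0.1 | weight of the PSNR regularization |
| `max_value`, `epsilon` | 255, 1e−4 | PSNR peak and MSE stability floor |
| `lr_init → lr_final` | 1e−4 → 1e−5 | cosine annealing, shared by G and D |
| `batch_size` | 8 | per optimization step |
| `crop_hr` | 256 | aligned HR training crop (LR crop = crop/s) |
| epochs (reference) | 800 | full-scale schedule length |

The head count and layer count are stated constants of the reference
configuration; the channel plan, token dimension and `K = 8` are
conventional choices where the reference leaves internal widths open, and
all are configurable.

## 3. Pinned numerical dialects

Several operations admit multiple common dialects; one is pinned so that
fixtures are bit-stable and "exact LR consistency" is well defined:

* **Bicubic**: separable Catmull-Rom (`a = −0.5`); on downscale the
  kernel support is stretched by the scale factor (antialiasing); borders
  mirror-reflect without repeating the edge sample; per-pixel weight
  normalization (constants are preserved exactly). The *same* operator
  builds training pairs and sits inside every LR-* metric — that identity
  is what makes the ε-capped LR-PSNR a bit-exactness certificate.
* **SSIM**: single-scale, 11×11 Gaussian window σ = 1.5, K1 = 0.01,
  K2 = 0.03, dynamic range 255, valid-region mean (no padded windows).
* **GradCons**: unnormalized 3×3 Sobel kernels, both orientations,
  mirror borders, unit-range intensities.
* **HF-Err**: 4-neighbor Laplacian `[[0,1,0],[1,−4,1],[0,1,0]]`, mirror
  borders, unit range.
* **Quantization**: `write_image` clamps to [0, 255] and rounds
  half-to-even; training-time PSNR uses the continuous byte scale
  (network output × 255) with no quantization.
* **P in the MSE**: the per-sample MSE divides by
  `channels · H_out · W_out`. The RGB-specific constant 3 is not
  hard-coded; grayscale fixtures use channels = 1.
* **LR-LPIPS**: exposed as a plugin slot on `evaluate_pairs` (a callable
  taking the re-degraded output and the LR input); no implementation is
  bundled because it requires externally trained perceptual weights.

The ε floor makes the PSNR loss *locally flat* for near-perfect
reconstructions (gradient exactly zero below MSE = 1e−4). This is the
objective as specified, kept as-is rather than "fixed"; the flat region
is unreachable in practice during training.

## 4. Open design points and how they were resolved

* **LR→HR bridging**: pre-upsampling with global residual learning. It
  makes "zero network = bicubic baseline" an exact, testable anchor (a
  zero-initialized final convolution reproduces the clamped bicubic
  upsample bit for bit) and keeps the U-Net resolution-preserving.
* **Attention sublayers**: residual + MSA only. An optional pre-norm
  variant was considered and rejected to keep the exact no-op property
  and the literal reading of the update rule.
* **Discriminator head**: global average pooling to one scalar (the
  simplest reading of a scalar `D(x)`), not a patch map.
* **Alternation**: one discriminator step per generator step; the
  generator uses fresh scores, not the ones from the discriminator step.
* **Adam**: β = (0.9, 0.999), shared cosine schedule for both networks.
* **Nonlinearity and resampling inside the U-Net**: LeakyReLU(0.2),
  stride-2 convolution down, nearest-neighbor + convolution up (avoids
  checkerboard artifacts).
* **Training crops**: crops are sampled on the LR grid and scaled by `s`,
  so every LR/HR crop pair stays aligned with the degradation model. The
  LR crop is *not* re-degraded from the HR crop; near crop borders
  `Down(hr_crop) ≠ lr_crop` because the degradation operator is global —
  the pairing, not per-crop re-degradation, is what training uses.
* **Tiled inference**: tiles on the LR grid, linear-ramp blending over
  the overlap, normalized coverage. For tile-local (purely convolutional)
  models the blend is exact away from tile edges; because the bottleneck
  attention is global, a tile sees only its own context, so tiled and
  single-pass outputs can differ beyond seam tolerance for arbitrary
  weights. When exactness matters and memory allows, use a tile covering
  the image.

## 5. Synthetic data: what it emulates and what it does not

`make_synthetic_fundus` draws a near-black surround, a dark circular
retinal field, a brighter optic disc (radius `disc_radius_frac · size/2`)
at a plausible eccentric position, `n_vessel_roots` binary vessel trees
(quadratic Bézier segments, branch angles uniform in [15°, 50°], width
decaying by `width_decay` per generation, anti-aliased strokes), and
additive Gaussian sensor noise (σ = 3 on the byte scale), clamped to
[0, 255]. Defaults: size 256, 4 roots, depth 5, width 4, decay 0.8,
disc fraction 0.16. Everything is a pure function of the configuration
seed.

This emulates the *geometry and frequency content* that matter to the
pipeline — genuine high-frequency structure (tests assert the Laplacian
energy of a fixture exceeds that of its own 8× down-up reconstruction),
curvilinear anatomy, a bright landmark, noise. It does **not** emulate
color, pathology (lesions, hemorrhages), illumination gradients,
vignetting, or camera optics. Consequently, passing tests demonstrate
that the algorithms and optimization behave as specified on fundus-like
statistics; they say nothing about clinical image quality, which requires
real data through the same interfaces.

## 6. Fixture-scale study sizes

All tests run on one CPU. The problem sizes are the package's CI-scale
choices, with the scale factor — the scientifically meaningful quantity —
kept at its reference value s = 8 throughout:

* fixtures 256² (smoke training) and 128² (ablation) rather than 2048²;
  the degradation-shape contract itself is still exercised at 2048² once;
* tiny network widths (base 6 channels, d = 12, T = 2, K = 4; 3 scales);
* smoke training: 8 pairs, batch 8, HR crop 32, 200 optimization steps;
* ablation: 8 training pairs, 2 held-out, 60 steps per loss mode,
  3 seeds × {hybrid, adv_only}.

For these tiny models the fixture learning rate is 3e−3 (cosine to
3e−4): a diagnostic sweep in `psnr_only` mode showed 1e−3 too slow to
express learning within 200 steps and 1e−2 unstable, while 3e−3 gives a
reliable PSNR improvement. The full-scale default remains
1e−4 → 1e−5.

Two training-dynamics facts shape the acceptance-style tests:

* The *hybrid* generator loss is not monotone over a short run: the
  adversarial term starts near 0 (the freshly initialized discriminator
  scores everything 0) and rises toward its hinge plateau (+1) as the
  discriminator warms up — ordinary early-GAN behavior that a 200-step
  run cannot outrun. The smoke regression therefore tracks the
  PSNR-regularized objective (`psnr_only` mode, where the generator loss
  *is* the PSNR term), the component whose decrease signals convergence
  on the training curve; the adversarial dynamics are exercised by the
  ablation test instead.
* The ablation direction — hybrid training preserves held-out LR-PSNR at
  least as well as adversarial-only training — is large and robust at
  fixture scale (adversarial-only collapses LR consistency within tens of
  steps, which is precisely the hallucination failure mode the hybrid
  loss exists to prevent).

## 7. Degenerate inputs, errors, determinism

Contract errors (not silent fixes) for: HR sizes not divisible by `s`;
crop or input sizes incompatible with `2^scales`; byte/unit range
mismatches; empty batches; misaligned lists; images smaller than the SSIM
window; `tile ≤ overlap`; corrupt checkpoints. `epochs = 0` returns
initialized models and an empty log. `K = 0` global tokens and `T = 0`
layers are valid degenerate configurations. Training, fixture generation
and splitting are pure functions of their seeds; two runs with identical
configuration produce identical logs and parameters on one device.

## 8. Known limitations

* No GPU path and no mixed precision; the base-R stack is intended for
  CI-scale models and method study, not 800-epoch full-scale training
  (the configuration for that scale is expressible, only slow).
* LR-LPIPS is a plugin slot only.
* Single integer scale factor per model; no 3D volumes; no windowed or
  linear attention variants.
* The bicubic dialect is pinned; numbers produced under other dialects
  (e.g., non-antialiased downsampling) are not comparable bit-for-bit.
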