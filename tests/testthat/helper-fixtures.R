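# Shared tiny model configurations and lazily generated fixture data.

tiny_gen_cfg <- function(scale_factor = 8L, scales = 3L) {
  gt_unet_config(scales = scales, base_channels = 6L, token_dim = 12L,
                 heads = 2L, layers = 2L, global_tokens = 4L,
                 scale_factor = scale_factor, channels = 1L)
}

tiny_disc_cfg <- function(input_side = 32L) {
  vgg_disc_config(blocks = 3L, base_channels = 4L, input_side = input_side,
                  channels = 1L)
}

.fixture_env <- new.env()

# 8 paired samples, 256^2 HR, s = 8 (the smoke-training fixture set)
smoke_samples <- function() {
  if (is.null(.fixture_env$smoke)) {
    cfg <- synthetic_fundus_config(size = 256, seed = 1)
    .fixture_env$smoke <- make_fixture_dataset(8, cfg, s = 8)
  }
  .fixture_env$smoke
}

# 10 paired samples, 128^2 HR, s = 8 (ablation train + held-out)
ablation_samples <- function() {
  if (is.null(.fixture_env$abl)) {
    cfg <- synthetic_fundus_config(size = 128, seed = 100)
    .fixture_env$abl <- make_fixture_dataset(10, cfg, s = 8)
  }
  .fixture_env$abl
}

# frozen regression row: bicubic-baseline metrics on the fixed synthetic
# fundus pair (size 128, seed 56, s = 8), computed once with the pinned
# resampler and metric dialects
.gtsr_baseline_row <- list(
  psnr = 21.85210189,
  ssim = 0.5884249572,
  lr_psnr = 33.63200327,
  lr_ssim = 0.9868423074,
  grad_cons = 0.03463582609,
  hf_err = 0.071937101
)

random_image <- function(h, w, ch = 1L, range = "byte", seed = 7L) {
  withr::with_seed(seed, {
    hi <- if (range == "byte") 255 else 1
    sr_image(array(stats::runif(ch * h * w, 0, hi), c(ch, h, w)), range)
  })
}
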