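#' Discriminator configuration
#'
#' A lightweight VGG-style convolutional discriminator: `blocks`
#' repetitions of \[3x3 conv + LeakyReLU(0.2), 3x3 stride-2 conv +
#' LeakyReLU(0.2)\], channels doubling from `base_channels` and capped at
#' `8 * base_channels` (the classic 32-64-128-256-256 plan at the
#' defaults), followed by spatial global-average pooling and an affine map
#' to a single raw realness score. No sigmoid and no batch normalization:
#' the hinge loss wants an unbounded score. At the defaults the parameter
#' count is well below the generator's, which is what makes it
#' "lightweight".
#'
#' @param blocks number of conv/downsample blocks.
#' @param base_channels channels of the first block.
#' @param input_side expected square input side in pixels (HR crop size).
#' @param channels image channels (1 or 3).
#' @return a `vgg_disc_config` list.
#' @export
vgg_disc_config <- function(blocks = 5L, base_channels = 32L,
                            input_side = 256L, channels = 1L) {
  if (blocks < 1L) stop("blocks must be >= 1")
  if (input_side < 2^blocks) {
    stop("input_side ", input_side, " too small for ", blocks,
         " stride-2 blocks")
  }
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3")
  structure(list(blocks = as.integer(blocks),
                 base_channels = as.integer(base_channels),
                 input_side = as.integer(input_side),
                 channels = as.integer(channels)),
            class = "vgg_disc_config")
}

disc_channels <- function(cfg) {
  pmin(cfg$base_channels * 2^(seq_len(cfg$blocks) - 1L),
       8L * cfg$base_channels)
}

#' Initialize a discriminator model
#'
#' He-initialized convolutions; the scoring head is zero-initialized so an
#' untrained discriminator scores every image 0 (neutral for the hinge
#' margins). Draws from the current RNG state.
#'
#' @param cfg a [vgg_disc_config].
#' @return a `discriminator_model`: list with flat `params` and `config`.
#' @export
init_discriminator <- function(cfg) {
  if (!inherits(cfg, "vgg_disc_config")) stop("expected a vgg_disc_config")
  ch <- disc_channels(cfg)
  p <- list()
  cin <- cfg$channels
  for (j in seq_len(cfg$blocks)) {
    c1 <- init_conv(cin, ch[j])
    p[[paste0("blk", j, ".c1.W")]] <- c1$W
    p[[paste0("blk", j, ".c1.b")]] <- c1$b
    c2 <- init_conv(ch[j], ch[j])
    p[[paste0("blk", j, ".c2.W")]] <- c2$W
    p[[paste0("blk", j, ".c2.b")]] <- c2$b
    cin <- ch[j]
  }
  p[["head.w"]] <- numeric(cin)
  p[["head.b"]] <- 0
  structure(list(params = p, config = cfg), class = "discriminator_model")
}

# cached forward from an N x C matrix on an h x w grid to a scalar score
disc_forward_cached <- function(params, cfg, mat, h, w) {
  caches <- list()
  x <- mat
  for (j in seq_len(cfg$blocks)) {
    cv1 <- conv3_forward(x, h, w, params[[paste0("blk", j, ".c1.W")]],
                         params[[paste0("blk", j, ".c1.b")]])
    a1 <- lrelu_forward(cv1$out)
    cv2 <- conv3_forward(a1$out, h, w, params[[paste0("blk", j, ".c2.W")]],
                         params[[paste0("blk", j, ".c2.b")]], stride = 2L)
    a2 <- lrelu_forward(cv2$out)
    caches[[paste0("blk", j)]] <- list(c1 = cv1$cache, a1 = a1$cache,
                                       c2 = cv2$cache, a2 = a2$cache)
    x <- a2$out; h <- cv2$h; w <- cv2$w
  }
  gap <- colMeans(x)
  score <- sum(gap * params[["head.w"]]) + params[["head.b"]]
  caches$gap_n <- nrow(x)
  caches$gap <- gap
  caches$head_w <- params[["head.w"]]
  caches$cfg <- cfg
  list(score = score, caches = caches)
}

# backward from d(score) to parameter grads and the input-image gradient
disc_backward <- function(caches, dscore) {
  cfg <- caches$cfg
  grads <- list()
  grads[["head.w"]] <- dscore * caches$gap
  grads[["head.b"]] <- dscore
  n <- caches$gap_n
  dx <- matrix(rep(dscore * caches$head_w / n, each = n), nrow = n)
  for (j in rev(seq_len(cfg$blocks))) {
    cc <- caches[[paste0("blk", j)]]
    da2 <- lrelu_backward(cc$a2, dx)
    b2 <- conv3_backward(cc$c2, da2)
    grads[[paste0("blk", j, ".c2.W")]] <- b2$dW
    grads[[paste0("blk", j, ".c2.b")]] <- b2$db
    da1 <- lrelu_backward(cc$a1, b2$dF)
    b1 <- conv3_backward(cc$c1, da1)
    grads[[paste0("blk", j, ".c1.W")]] <- b1$dW
    grads[[paste0("blk", j, ".c1.b")]] <- b1$db
    dx <- b1$dF
  }
  list(dIn = dx, grads = grads)
}

#' Score an image with the discriminator
#'
#' Returns the raw (unbounded) realness score used by the hinge loss.
#' Deterministic given parameters and input.
#'
#' @param img an [sr_image] in unit range whose side equals the configured
#'   `input_side`.
#' @param model a `discriminator_model` from [init_discriminator].
#' @return a single numeric score.
#' @export
discriminator_forward <- function(img, model) {
  stopifnot_range(img, "unit")
  cfg <- model$config
  if (img_channels(img) != cfg$channels) {
    stop("model expects ", cfg$channels, "-channel input")
  }
  if (img_height(img) != cfg$input_side || img_width(img) != cfg$input_side) {
    stop("discriminator expects ", cfg$input_side, "x", cfg$input_side,
         " input, got ", img_height(img), "x", img_width(img))
  }
  disc_forward_cached(model$params, cfg, feat_to_mat(img$pixels),
                      img_height(img), img_width(img))$score
}
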