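#' Generator configuration
#'
#' The generator is a pre-upsampling U-Net: the LR input is bicubically
#' interpolated to the HR grid, a U-shaped encoder-decoder with skip
#' connections predicts a residual, and the output is
#' `clamp01(upsampled + residual)`. The bottleneck feature is refined by
#' the global-token attention stack. Encoder channels double per scale,
#' capped at `8 * base_channels`. With the final convolution zero-initialized
#' the untrained generator reproduces the bicubic baseline exactly — a
#' testable anchor.
#'
#' @param scales number of down/upsampling stages (stride-2 / nearest x2).
#' @param base_channels channels after the head convolution.
#' @param token_dim token dimension d at the bottleneck.
#' @param heads attention heads M (must divide `token_dim`); default 4.
#' @param layers residual MSA layers T; default 4.
#' @param global_tokens learned global token count K.
#' @param scale_factor integer super-resolution factor s.
#' @param channels image channels (1 grayscale, 3 RGB).
#' @return a `gt_unet_config` list.
#' @export
gt_unet_config <- function(scales = 4L, base_channels = 32L, token_dim = 256L,
                           heads = 4L, layers = 4L, global_tokens = 8L,
                           scale_factor = 8L, channels = 1L) {
  if (scales < 1L) stop("scales must be >= 1")
  if (token_dim %% heads != 0L) {
    stop("heads (", heads, ") must divide token_dim (", token_dim, ")")
  }
  if (layers < 0L) stop("layers must be >= 0")
  if (global_tokens < 0L) stop("global_tokens must be >= 0")
  if (scale_factor < 1L) stop("scale_factor must be >= 1")
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3")
  structure(list(scales = as.integer(scales),
                 base_channels = as.integer(base_channels),
                 token_dim = as.integer(token_dim),
                 heads = as.integer(heads), layers = as.integer(layers),
                 global_tokens = as.integer(global_tokens),
                 scale_factor = as.integer(scale_factor),
                 channels = as.integer(channels)),
            class = "gt_unet_config")
}

# encoder channel plan: ch[1] after head, ch[i+1] at scale i
gen_channels <- function(cfg) {
  pmin(cfg$base_channels * 2^(0:cfg$scales), 8L * cfg$base_channels)
}

#' Initialize a generator model
#'
#' He-initialized convolutions, small-normal attention projections and
#' global tokens, and a zero-initialized final convolution so the freshly
#' initialized generator is exactly the bicubic-upsampling baseline.
#' Draws from the current RNG state; seed beforehand for reproducibility.
#'
#' @param cfg a [gt_unet_config].
#' @return a `generator_model`: list with flat `params` and `config`.
#' @export
init_generator <- function(cfg) {
  if (!inherits(cfg, "gt_unet_config")) stop("expected a gt_unet_config")
  ch <- gen_channels(cfg)
  p <- list()
  put_conv <- function(p, name, cin, cout, zero = FALSE) {
    cv <- init_conv(cin, cout)
    if (zero) cv$W[] <- 0
    p[[paste0(name, ".W")]] <- cv$W
    p[[paste0(name, ".b")]] <- cv$b
    p
  }
  p <- put_conv(p, "head", cfg$channels, ch[1])
  for (i in seq_len(cfg$scales)) {
    p <- put_conv(p, paste0("enc", i, ".down"), ch[i], ch[i + 1])
    p <- put_conv(p, paste0("enc", i, ".conv"), ch[i + 1], ch[i + 1])
  }
  cb <- ch[cfg$scales + 1L]
  p <- put_conv(p, "gt.tok", cb, cfg$token_dim)
  p[["gt.G0"]] <- matrix(stats::rnorm(cfg$global_tokens * cfg$token_dim,
                                      sd = 0.02),
                         cfg$global_tokens, cfg$token_dim)
  if (cfg$layers > 0L) {
    for (t in seq_len(cfg$layers)) {
      al <- init_attention_layer(cfg$token_dim, cfg$heads)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0("gt.l", t, ".", nm)]] <- al[[nm]]
      }
    }
  }
  p <- put_conv(p, "gt.detok", cfg$token_dim, cb)
  for (i in rev(seq_len(cfg$scales))) {
    p <- put_conv(p, paste0("dec", i, ".up"), ch[i + 1], ch[i])
    p <- put_conv(p, paste0("dec", i, ".fuse"), 2L * ch[i], ch[i])
  }
  p <- put_conv(p, "final", ch[1], cfg$channels, zero = TRUE)
  structure(list(params = p, config = cfg), class = "generator_model")
}

# full cached forward pass; lr_mat is the pre-upsampled input as an
# N x channels matrix on the HR grid (h x w)
gen_forward_cached <- function(params, cfg, up_mat, h, w) {
  caches <- list()
  cv <- conv3_forward(up_mat, h, w, params[["head.W"]], params[["head.b"]])
  ac <- lrelu_forward(cv$out)
  caches$head <- list(conv = cv$cache, act = ac$cache)
  x <- ac$out
  skips <- list(); dims <- list()
  hh <- h; ww <- w
  for (i in seq_len(cfg$scales)) {
    skips[[i]] <- x; dims[[i]] <- c(hh, ww)
    cv <- conv3_forward(x, hh, ww, params[[paste0("enc", i, ".down.W")]],
                        params[[paste0("enc", i, ".down.b")]], stride = 2L)
    ac <- lrelu_forward(cv$out)
    cv2 <- conv3_forward(ac$out, cv$h, cv$w,
                         params[[paste0("enc", i, ".conv.W")]],
                         params[[paste0("enc", i, ".conv.b")]])
    ac2 <- lrelu_forward(cv2$out)
    caches[[paste0("enc", i)]] <- list(down = cv$cache, a1 = ac$cache,
                                       conv = cv2$cache, a2 = ac2$cache)
    x <- ac2$out; hh <- cv$h; ww <- cv$w
  }
  gts <- gts_forward(x, hh, ww, params, heads = cfg$heads,
                     layers = cfg$layers, k = cfg$global_tokens)
  caches$gts <- gts$cache
  x <- gts$out
  for (i in rev(seq_len(cfg$scales))) {
    up <- upsample2_forward(x, hh, ww)
    hh <- up$h; ww <- up$w
    cv <- conv3_forward(up$out, hh, ww, params[[paste0("dec", i, ".up.W")]],
                        params[[paste0("dec", i, ".up.b")]])
    ac <- lrelu_forward(cv$out)
    cat_in <- cbind(ac$out, skips[[i]])
    cv2 <- conv3_forward(cat_in, hh, ww, params[[paste0("dec", i, ".fuse.W")]],
                         params[[paste0("dec", i, ".fuse.b")]])
    ac2 <- lrelu_forward(cv2$out)
    caches[[paste0("dec", i)]] <- list(up = up$cache, conv = cv$cache,
                                       a1 = ac$cache, fuse = cv2$cache,
                                       a2 = ac2$cache,
                                       n_up = ncol(ac$out))
    x <- ac2$out
  }
  cv <- conv3_forward(x, h, w, params[["final.W"]], params[["final.b"]])
  caches$final <- cv$cache
  v <- up_mat + cv$out
  out <- pmin(pmax(v, 0), 1)
  caches$clamp_mask <- v > 0 & v < 1
  caches$cfg <- cfg
  list(out = out, caches = caches)
}

gen_backward <- function(caches, dOut) {
  cfg <- caches$cfg
  grads <- list()
  d <- dOut * caches$clamp_mask
  fb <- conv3_backward(caches$final, d)
  grads[["final.W"]] <- fb$dW; grads[["final.b"]] <- fb$db
  dx <- fb$dF
  dskips <- list()
  for (i in seq_len(cfg$scales)) {
    cc <- caches[[paste0("dec", i)]]
    da <- lrelu_backward(cc$a2, dx)
    fu <- conv3_backward(cc$fuse, da)
    grads[[paste0("dec", i, ".fuse.W")]] <- fu$dW
    grads[[paste0("dec", i, ".fuse.b")]] <- fu$db
    n_up <- cc$n_up
    d_up_branch <- fu$dF[, seq_len(n_up), drop = FALSE]
    dskips[[i]] <- fu$dF[, -seq_len(n_up), drop = FALSE]
    da1 <- lrelu_backward(cc$a1, d_up_branch)
    cb <- conv3_backward(cc$conv, da1)
    grads[[paste0("dec", i, ".up.W")]] <- cb$dW
    grads[[paste0("dec", i, ".up.b")]] <- cb$db
    dx <- upsample2_backward(cc$up, cb$dF)
  }
  gb <- gts_backward(caches$gts, dx)
  grads <- c(grads, gb$grads)
  dx <- gb$dF
  for (i in rev(seq_len(cfg$scales))) {
    cc <- caches[[paste0("enc", i)]]
    da2 <- lrelu_backward(cc$a2, dx)
    cb2 <- conv3_backward(cc$conv, da2)
    grads[[paste0("enc", i, ".conv.W")]] <- cb2$dW
    grads[[paste0("enc", i, ".conv.b")]] <- cb2$db
    da1 <- lrelu_backward(cc$a1, cb2$dF)
    cb <- conv3_backward(cc$down, da1)
    grads[[paste0("enc", i, ".down.W")]] <- cb$dW
    grads[[paste0("enc", i, ".down.b")]] <- cb$db
    dx <- cb$dF + dskips[[i]]
  }
  da <- lrelu_backward(caches$head$act, dx)
  hb <- conv3_backward(caches$head$conv, da)
  grads[["head.W"]] <- hb$dW; grads[["head.b"]] <- hb$db
  grads
}

#' Super-resolve an LR image with the generator
#'
#' Pre-upsamples the unit-range LR input bicubically by the configured
#' scale factor, runs the U-Net with global-token bottleneck, and returns
#' `clamp01(upsampled + residual)` as a unit-range image of `s` times the
#' input size. Deterministic given parameters and input.
#'
#' @param y an [sr_image] in unit range.
#' @param model a `generator_model` from [init_generator].
#' @return an [sr_image] in unit range, `s * dim(y)`.
#' @export
generator_forward <- function(y, model) {
  stopifnot_range(y, "unit")
  cfg <- model$config
  if (img_channels(y) != cfg$channels) {
    stop("model expects ", cfg$channels, "-channel input")
  }
  s <- cfg$scale_factor
  h <- s * img_height(y); w <- s * img_width(y)
  div <- 2^cfg$scales
  if (h %% div != 0L || w %% div != 0L) {
    stop("pre-upsampled size ", h, "x", w, " must be divisible by 2^scales = ",
         div)
  }
  up <- bicubic_resample(y, h, w)
  up$pixels <- pmin(pmax(up$pixels, 0), 1)  # bicubic can overshoot
  res <- gen_forward_cached(model$params, cfg, feat_to_mat(up$pixels), h, w)
  sr_image(mat_to_feat(res$out, cfg$channels, h, w), range = "unit")
}
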