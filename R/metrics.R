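# Evaluation metrics: full-reference PSNR/SSIM against the HR ground
# truth, and the LR-consistency trustworthiness family computed by
# re-degrading the SR output with the SAME pinned bicubic operator used to
# build the training pairs and comparing against the LR input. Using the
# identical downsampler is what makes perfect LR consistency attainable
# (and detectable: LR-PSNR hits its epsilon cap iff Down(xhat) == y).

#' Peak signal-to-noise ratio between two byte-range images
#'
#' Identical formula to [per_sample_psnr] (M = 255, MSE floored at 1e-4);
#' exposed as the evaluation entry point.
#'
#' @param xhat,x [sr_image]s in byte range, same shape.
#' @return PSNR in dB.
#' @export
metric_psnr <- function(xhat, x) per_sample_psnr(xhat, x, loss_config())

# 1D Gaussian window, length 11, sigma 1.5, normalized
ssim_window <- function() {
  t <- seq(-5, 5)
  g <- exp(-t^2 / (2 * 1.5^2))
  g / sum(g)
}

# valid-convolution matrix applying the window along one axis
valid_conv_matrix <- function(n, g) {
  k <- length(g)
  if (n < k) stop("image side ", n, " smaller than the ", k, "-tap window")
  m <- matrix(0, n - k + 1L, n)
  for (i in seq_len(n - k + 1L)) m[i, i:(i + k - 1L)] <- g
  m
}

#' Structural similarity index (SSIM)
#'
#' Standard single-scale SSIM: 11x11 Gaussian window (sigma 1.5),
#' K1 = 0.01, K2 = 0.03, dynamic range 255, computed per channel on the
#' valid region (windows fully inside the image) and averaged over
#' positions and channels. Symmetric in its arguments; equals 1 iff the
#' images are identical.
#'
#' @param xhat,x [sr_image]s in byte range, same shape, sides >= 11.
#' @return SSIM in \[-1, 1\].
#' @export
metric_ssim <- function(xhat, x) {
  stopifnot_range(xhat, "byte"); stopifnot_range(x, "byte")
  if (!identical(dim(xhat$pixels), dim(x$pixels))) stop("shape mismatch")
  h <- img_height(x); w <- img_width(x)
  g <- ssim_window()
  Wr <- valid_conv_matrix(h, g)
  Wc <- valid_conv_matrix(w, g)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  win <- function(m) Wr %*% m %*% t(Wc)
  vals <- vapply(seq_len(img_channels(x)), function(ch) {
    a <- xhat$pixels[ch, , ]; b <- x$pixels[ch, , ]
    mu_a <- win(a); mu_b <- win(b)
    var_a <- win(a * a) - mu_a^2
    var_b <- win(b * b) - mu_b^2
    cov_ab <- win(a * b) - mu_a * mu_b
    ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
    mean(ssim_map)
  }, numeric(1))
  mean(vals)
}

#' LR-consistency metrics: LR-PSNR and LR-SSIM
#'
#' Downsamples the super-resolved image back to the input resolution with
#' the package's pinned bicubic operator and scores it against the
#' original LR input. High values mean the SR output is faithful to the
#' observation it was computed from — the trustworthiness criterion.
#' LR-PSNR reaches its epsilon cap exactly when `Down(xhat)` equals `y`
#' bit for bit.
#'
#' @param xhat super-resolved [sr_image], byte range.
#' @param y original LR input [sr_image], byte range; `dim(xhat)` must be
#'   `s * dim(y)`.
#' @param s integer scale factor (s = 1 reduces to plain PSNR/SSIM).
#' @return named list with `lr_psnr` (dB) and `lr_ssim`.
#' @export
lr_consistency <- function(xhat, y, s) {
  d <- downsampled_for_metric(xhat, y, s)
  list(lr_psnr = metric_psnr(d, y), lr_ssim = metric_ssim(d, y))
}

downsampled_for_metric <- function(xhat, y, s) {
  s <- as.integer(s)
  if (img_height(xhat) != s * img_height(y) ||
      img_width(xhat) != s * img_width(y)) {
    stop("xhat dimensions must be exactly s = ", s, " times y dimensions")
  }
  if (s == 1L) xhat else bicubic_resample(xhat, img_height(y), img_width(y))
}

# 3x3 filtering with mirror borders on an H x W matrix; kernel indexed
# [di+2, dj+2] for offsets di, dj in -1:1
filter3_mirror <- function(m, kernel) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (di in -1:1) {
    ri <- mirror_index(seq_len(h) + di, h)
    for (dj in -1:1) {
      k <- kernel[di + 2L, dj + 2L]
      if (k == 0) next
      ci <- mirror_index(seq_len(w) + dj, w)
      out <- out + k * m[ri, ci]
    }
  }
  out
}

sobel_x_kernel <- function() matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3,
                                    byrow = TRUE)
sobel_y_kernel <- function() t(sobel_x_kernel())
laplacian_kernel <- function() matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3,
                                      byrow = TRUE)

#' Gradient consistency (GradCons)
#'
#' Mean absolute difference between the Sobel gradient fields of
#' `Down(xhat)` and `y`, with both images first normalized to the unit
#' range. The standard unnormalized 3x3 Sobel kernels (horizontal and
#' vertical) are applied with mirror borders; the mean runs over all
#' pixels, channels and both orientations. Zero-sum kernels make the
#' metric invariant to constant intensity offsets.
#'
#' @inheritParams lr_consistency
#' @return nonnegative scalar (unit-range intensity gradient units).
#' @export
grad_cons <- function(xhat, y, s) {
  d <- downsampled_for_metric(xhat, y, s)
  du <- d$pixels / 255; yu <- y$pixels / 255
  kx <- sobel_x_kernel(); ky <- sobel_y_kernel()
  errs <- vapply(seq_len(img_channels(y)), function(ch) {
    ex <- abs(filter3_mirror(du[ch, , ], kx) - filter3_mirror(yu[ch, , ], kx))
    ey <- abs(filter3_mirror(du[ch, , ], ky) - filter3_mirror(yu[ch, , ], ky))
    mean(c(ex, ey))
  }, numeric(1))
  mean(errs)
}

#' High-frequency error (HF-Err)
#'
#' Mean absolute difference between the 4-neighbor Laplacian responses of
#' `Down(xhat)` and `y` on the unit range, mirror borders. The Laplacian
#' annihilates constant (and, away from borders, affine) intensity
#' fields, so the metric isolates genuine high-frequency disagreement.
#'
#' @inheritParams lr_consistency
#' @return nonnegative scalar.
#' @export
hf_err <- function(xhat, y, s) {
  d <- downsampled_for_metric(xhat, y, s)
  du <- d$pixels / 255; yu <- y$pixels / 255
  kl <- laplacian_kernel()
  errs <- vapply(seq_len(img_channels(y)), function(ch) {
    mean(abs(filter3_mirror(du[ch, , ], kl) - filter3_mirror(yu[ch, , ], kl)))
  }, numeric(1))
  mean(errs)
}

#' Evaluate SR outputs over a paired dataset
#'
#' Computes the full metric report (PSNR, SSIM against HR; LR-PSNR,
#' LR-SSIM, GradCons, HF-Err against the LR input) for each sample and
#' the mean over the set.
#'
#' @param samples list of `paired_sample`s (see [degrade]).
#' @param sr_outputs list of byte-range [sr_image]s aligned with
#'   `samples`.
#' @param lpips optional plugin: a function `(downsampled_sr, lr) ->
#'   scalar` filling the `lr_lpips` column (requires externally supplied
#'   perceptual weights; no implementation is bundled).
#' @return list with `per_sample` (data.frame: id + metric columns) and
#'   `mean` (named numeric vector).
#' @export
evaluate_pairs <- function(samples, sr_outputs, lpips = NULL) {
  if (length(samples) == 0L) stop("empty sample list")
  if (length(samples) != length(sr_outputs)) {
    stop("samples and sr_outputs are misaligned")
  }
  rows <- lapply(seq_along(samples), function(i) {
    sm <- samples[[i]]; out <- sr_outputs[[i]]
    lrc <- lr_consistency(out, sm$lr, sm$s)
    row <- data.frame(id = sm$id,
                      psnr = metric_psnr(out, sm$hr),
                      ssim = metric_ssim(out, sm$hr),
                      lr_psnr = lrc$lr_psnr,
                      lr_ssim = lrc$lr_ssim,
                      grad_cons = grad_cons(out, sm$lr, sm$s),
                      hf_err = hf_err(out, sm$lr, sm$s),
                      stringsAsFactors = FALSE)
    if (!is.null(lpips)) {
      row$lr_lpips <- lpips(downsampled_for_metric(out, sm$lr, sm$s), sm$lr)
    }
    row
  })
  per_sample <- do.call(rbind, rows)
  means <- colMeans(per_sample[, setdiff(names(per_sample), "id"),
                               drop = FALSE])
  list(per_sample = per_sample, mean = means)
}
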