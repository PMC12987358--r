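#' Loss configuration
#'
#' Constants of the hybrid training objective: the PSNR regularization
#' weight (default 0.1), the peak pixel value M = 255, the MSE stability
#' floor epsilon = 1e-4, and the loss mode used by the ablation switch.
#'
#' @param lambda_psnr nonnegative weight on the PSNR regularization term;
#'   must be positive in hybrid mode.
#' @param max_value peak pixel value M on the byte scale.
#' @param epsilon stability floor applied to the per-sample MSE.
#' @param mode `"hybrid"` (adversarial + weighted PSNR), `"psnr_only"` or
#'   `"adv_only"` — the three ablation variants.
#' @return a `loss_config` list.
#' @export
loss_config <- function(lambda_psnr = 0.1, max_value = 255, epsilon = 1e-4,
                        mode = c("hybrid", "psnr_only", "adv_only")) {
  mode <- match.arg(mode)
  if (lambda_psnr < 0) stop("lambda_psnr must be >= 0")
  if (mode == "hybrid" && lambda_psnr <= 0) {
    stop("hybrid mode requires lambda_psnr > 0")
  }
  if (max_value <= 0 || epsilon <= 0) stop("max_value and epsilon must be > 0")
  structure(list(lambda_psnr = lambda_psnr, max_value = max_value,
                 epsilon = epsilon, mode = mode),
            class = "loss_config")
}

#' Hinge discriminator loss
#'
#' `mean over i of max(0, 1 - real_i) + max(0, 1 + fake_i)`: real images
#' are pushed above the +1 margin and generated images below the -1
#' margin. Always nonnegative; zero exactly when every margin is
#' satisfied.
#'
#' @param real_scores,fake_scores numeric vectors of equal length B >= 1
#'   of raw discriminator scores.
#' @return a single numeric loss.
#' @export
hinge_d_loss <- function(real_scores, fake_scores) {
  if (length(real_scores) == 0L || length(fake_scores) == 0L) {
    stop("empty score batch")
  }
  if (length(real_scores) != length(fake_scores)) {
    stop("real and fake batches must have equal length")
  }
  mean(pmax(0, 1 - real_scores) + pmax(0, 1 + fake_scores))
}

#' Generator adversarial loss
#'
#' The negative mean of the discriminator's scores on generated images:
#' the generator minimizes this by making its outputs score high.
#'
#' @param fake_scores numeric vector of length B >= 1.
#' @return a single numeric loss.
#' @export
adv_g_loss <- function(fake_scores) {
  if (length(fake_scores) == 0L) stop("empty score batch")
  -mean(fake_scores)
}

#' Per-sample PSNR with a stability floor
#'
#' `PSNR = 10 log10(M^2 / max(MSE, epsilon))` in dB, with
#' `MSE = |xhat - x|^2 / P` and `P = channels * H * W`. Both images must be
#' on the byte scale (M = 255 by default). The epsilon floor caps the PSNR
#' of a perfect reconstruction at `10 log10(255^2 / 1e-4)` (about
#' 88.13 dB) and makes the loss locally flat there.
#'
#' @param xhat,x [sr_image]s in byte range, same shape.
#' @param cfg a [loss_config].
#' @return PSNR in dB.
#' @export
per_sample_psnr <- function(xhat, x, cfg = loss_config()) {
  stopifnot_range(xhat, "byte"); stopifnot_range(x, "byte")
  if (!identical(dim(xhat$pixels), dim(x$pixels))) {
    stop("shape mismatch: ", paste(dim(xhat$pixels), collapse = "x"),
         " vs ", paste(dim(x$pixels), collapse = "x"))
  }
  mse <- mean((xhat$pixels - x$pixels)^2)
  10 * log10(cfg$max_value^2 / max(mse, cfg$epsilon))
}

#' PSNR regularization loss over a batch
#'
#' The negative batch mean of [per_sample_psnr]: minimizing it maximizes
#' the reconstruction PSNR. During training it is evaluated on the
#' continuous byte scale (network output times 255) without quantization.
#'
#' @param batch_xhat,batch_x lists of byte-range [sr_image]s, aligned.
#' @param cfg a [loss_config].
#' @return a single numeric loss (negative dB).
#' @export
psnr_loss <- function(batch_xhat, batch_x, cfg = loss_config()) {
  if (length(batch_xhat) == 0L) stop("empty batch")
  if (length(batch_xhat) != length(batch_x)) stop("misaligned batches")
  -mean(mapply(per_sample_psnr, batch_xhat, batch_x,
               MoreArgs = list(cfg = cfg)))
}

#' Combine the generator loss terms
#'
#' The combination step of the generator objective:
#' hybrid mode returns `l_adv_g + lambda_psnr * l_psnr`; the ablation
#' modes return the single corresponding term.
#'
#' @param l_adv_g adversarial term value.
#' @param l_psnr PSNR regularization term value.
#' @param cfg a [loss_config].
#' @return the combined generator loss `l_g`.
#' @export
combine_generator_loss <- function(l_adv_g, l_psnr, cfg = loss_config()) {
  switch(cfg$mode,
         hybrid = l_adv_g + cfg$lambda_psnr * l_psnr,
         psnr_only = l_psnr,
         adv_only = l_adv_g)
}

#' Full generator loss report
#'
#' Evaluates the adversarial term from the discriminator scores, the PSNR
#' term from the image batches, and their mode-dependent combination.
#'
#' @param fake_scores discriminator scores on the generated batch.
#' @param batch_xhat,batch_x lists of byte-range [sr_image]s, aligned with
#'   `fake_scores`.
#' @param cfg a [loss_config].
#' @return a `loss_report`: list with `l_adv_g`, `l_psnr`, `l_g`,
#'   `per_sample_psnr` (vector, dB), and `l_d` (`NA`; filled by the
#'   trainer, which owns the discriminator step).
#' @export
generator_loss <- function(fake_scores, batch_xhat, batch_x,
                           cfg = loss_config()) {
  if (length(fake_scores) != length(batch_xhat)) {
    stop("scores and image batch are misaligned")
  }
  psnrs <- mapply(per_sample_psnr, batch_xhat, batch_x,
                  MoreArgs = list(cfg = cfg))
  l_adv <- adv_g_loss(fake_scores)
  l_psnr <- -mean(psnrs)
  structure(list(l_d = NA_real_, l_adv_g = l_adv, l_psnr = l_psnr,
                 l_g = combine_generator_loss(l_adv, l_psnr, cfg),
                 per_sample_psnr = psnrs),
            class = "loss_report")
}

# gradient of the PSNR loss w.r.t. the unit-range generator output.
# xhat_unit/x_unit: (C,H,W) arrays in [0,1]. Byte scale enters through the
# factor 255; inside the epsilon floor the loss is flat and the gradient 0.
psnr_loss_grad_unit <- function(xhat_unit, x_unit, cfg, batch_size) {
  p <- length(xhat_unit)
  diff <- (xhat_unit - x_unit) * 255
  mse <- mean(diff^2)
  if (mse <= cfg$epsilon) {
    return(array(0, dim = dim(xhat_unit)))
  }
  # d(-PSNR/B)/dmse = 10 / (B * mse * ln 10); dmse/dxhat_unit = 2*255*diff/P
  (10 / (batch_size * mse * log(10))) * (2 * 255 * diff / p)
}
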