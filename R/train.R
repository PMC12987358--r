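#' Training configuration
#'
#' Optimization settings of the adversarial training loop. The reference
#' configuration is Adam (beta1 0.9, beta2 0.999), batch size 8, learning
#' rate cosine-annealed from 1e-4 to 1e-5, 800 epochs and HR crop 256;
#' the constructor defaults keep those constants except for a
#' fixture-scale epoch count so the loop is exercisable on one CPU.
#'
#' @param epochs training epochs (reference scale 800; default 50 for
#'   fixture-scale runs).
#' @param batch_size samples per optimization step.
#' @param lr_init,lr_final initial and final learning rates of the cosine
#'   schedule (shared by generator and discriminator).
#' @param beta1,beta2 Adam moment decay rates.
#' @param loss a [loss_config]; its `mode` is the ablation switch.
#' @param crop_hr side of the aligned HR training crops in pixels; must be
#'   divisible by the scale factor (crops are taken on the LR grid).
#' @param seed integer seed; two runs with identical configuration produce
#'   identical logs on one device.
#' @param d_steps_per_g_step discriminator steps per generator step.
#' @param checkpoint_every write a checkpoint every this many epochs (and
#'   at the end); `Inf` disables periodic checkpoints.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, lr_init = 1e-4,
                         lr_final = 1e-5, beta1 = 0.9, beta2 = 0.999,
                         loss = loss_config(), crop_hr = 256L, seed = 0L,
                         d_steps_per_g_step = 1L, checkpoint_every = Inf) {
  if (epochs < 0L) stop("epochs must be >= 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (lr_final > lr_init) stop("lr_final must be <= lr_init")
  if (d_steps_per_g_step < 1L) stop("d_steps_per_g_step must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_final = lr_final,
                 beta1 = beta1, beta2 = beta2, loss = loss,
                 crop_hr = as.integer(crop_hr), seed = as.integer(seed),
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 checkpoint_every = checkpoint_every),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `eta(t) = lr_final + (lr_init - lr_final) * (1 + cos(pi t / (E-1))) / 2`
#' for 0-based epoch `t` of `E` epochs: exactly `lr_init` at epoch 0,
#' exactly `lr_final` at the last epoch, and monotone non-increasing in
#' between.
#'
#' @param epoch 0-based epoch index in `[0, epochs - 1]`.
#' @param cfg a [train_config].
#' @return the learning rate at `epoch`.
#' @export
cosine_lr <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0) || any(epoch > cfg$epochs - 1L)) {
    stop("epoch must lie in [0, ", cfg$epochs - 1L, "]")
  }
  if (cfg$epochs == 1L) return(rep(cfg$lr_init, length(epoch)))
  cfg$lr_final + 0.5 * (cfg$lr_init - cfg$lr_final) *
    (1 + cos(pi * epoch / (cfg$epochs - 1L)))
}

# aligned random crop: position drawn on the LR grid, scaled by s for HR
sample_crop <- function(sample, crop_hr) {
  s <- sample$s
  cl <- crop_hr %/% s
  lh <- img_height(sample$lr); lw <- img_width(sample$lr)
  if (cl > lh || cl > lw) stop("crop_hr larger than the HR image")
  r0 <- if (lh == cl) 1L else sample.int(lh - cl + 1L, 1L)
  c0 <- if (lw == cl) 1L else sample.int(lw - cl + 1L, 1L)
  lr <- sr_image(sample$lr$pixels[, r0:(r0 + cl - 1L), c0:(c0 + cl - 1L),
                                  drop = FALSE], range = sample$lr$range)
  hr0 <- (r0 - 1L) * s; hc0 <- (c0 - 1L) * s
  hr <- sr_image(sample$hr$pixels[, (hr0 + 1L):(hr0 + crop_hr),
                                  (hc0 + 1L):(hc0 + crop_hr), drop = FALSE],
                 range = sample$hr$range)
  list(lr = lr, hr = hr)
}

#' Train the generator and discriminator adversarially
#'
#' Per optimization step: aligned LR/HR crops are sampled from the
#' training split; the discriminator takes a hinge-loss step on real HR
#' crops versus detached generator outputs; the generator then takes a
#' step on the mode-dependent objective (hybrid: adversarial + weighted
#' PSNR) using fresh discriminator scores. Both networks share one
#' cosine-annealed Adam schedule. Fully seeded: identical configurations
#' give bitwise-identical logs on one device. In `psnr_only` mode the
#' discriminator is neither trained nor evaluated and the adversarial
#' columns are `NA`.
#'
#' @param samples list of `paired_sample`s (see [degrade]).
#' @param cfg a [train_config].
#' @param gen_cfg a [gt_unet_config].
#' @param disc_cfg a [vgg_disc_config]; its `input_side` must equal
#'   `cfg$crop_hr`.
#' @param split optional `dataset_split`; only its `train` ids are used.
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @return list with `generator`, `discriminator`, and `log` (list of
#'   data.frames `epochs` and `steps`).
#' @export
train <- function(samples, cfg = train_config(), gen_cfg = gt_unet_config(),
                  disc_cfg = NULL, split = NULL, checkpoint_dir = NULL) {
  if (length(samples) == 0L) stop("no training samples")
  s <- samples[[1]]$s
  if (cfg$crop_hr %% s != 0L) {
    stop("crop_hr ", cfg$crop_hr, " must be divisible by scale factor ", s)
  }
  if (cfg$crop_hr %% 2^gen_cfg$scales != 0L) {
    stop("crop_hr must be divisible by 2^scales = ", 2^gen_cfg$scales)
  }
  if (gen_cfg$scale_factor != s) {
    stop("generator scale_factor (", gen_cfg$scale_factor,
         ") must match the dataset scale (", s, ")")
  }
  if (is.null(disc_cfg)) {
    disc_cfg <- vgg_disc_config(input_side = cfg$crop_hr,
                                channels = gen_cfg$channels)
  }
  if (disc_cfg$input_side != cfg$crop_hr) {
    stop("discriminator input_side must equal crop_hr")
  }
  ids <- vapply(samples, function(x) x$id, character(1))
  pool <- if (is.null(split)) samples else {
    missing <- setdiff(split$train, ids)
    if (length(missing)) stop("split references unknown ids: ",
                              paste(missing, collapse = ", "))
    samples[match(split$train, ids)]
  }
  if (length(pool) == 0L) stop("empty training split")
  mode <- cfg$loss$mode
  use_adv <- mode != "psnr_only"

  set.seed(cfg$seed)
  gen <- init_generator(gen_cfg)
  disc <- init_discriminator(disc_cfg)
  ad_g <- adam_init(gen$params)
  ad_d <- adam_init(disc$params)

  n <- length(pool)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  step_rows <- list(); epoch_rows <- list(); gstep <- 0L

  maybe_checkpoint <- function(epoch_done) {
    if (is.null(checkpoint_dir)) return(invisible(NULL))
    due <- is.finite(cfg$checkpoint_every) &&
      epoch_done %% cfg$checkpoint_every == 0L
    if (due || epoch_done == cfg$epochs) {
      save_checkpoint(file.path(checkpoint_dir,
                                sprintf("ckpt_epoch%04d.rds", epoch_done)),
                      gen, disc, cfg)
    }
    invisible(NULL)
  }

  crop_side_hr <- cfg$crop_hr
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr_now <- cosine_lr(epoch, cfg)
    order_idx <- sample.int(n)
    for (st in seq_len(steps_per_epoch)) {
      pos <- ((st - 1L) * cfg$batch_size + seq_len(cfg$batch_size) - 1L) %%
        n + 1L
      take <- order_idx[pos]
      crops <- lapply(pool[take], sample_crop, crop_hr = crop_side_hr)
      B <- length(crops)
      ups <- lapply(crops, function(cr) {
        up <- bicubic_resample(to_unit(cr$lr), crop_side_hr, crop_side_hr)
        up$pixels <- pmin(pmax(up$pixels, 0), 1)
        up
      })

      l_d <- NA_real_
      if (use_adv) {
        for (dstep in seq_len(cfg$d_steps_per_g_step)) {
          real_sc <- numeric(B); fake_sc <- numeric(B)
          d_grads <- NULL
          d_caches_real <- vector("list", B)
          d_caches_fake <- vector("list", B)
          for (i in seq_len(B)) {
            gf <- gen_forward_cached(gen$params, gen_cfg,
                                     feat_to_mat(ups[[i]]$pixels),
                                     crop_side_hr, crop_side_hr)
            real_mat <- feat_to_mat(crops[[i]]$hr$pixels / 255)
            dfr <- disc_forward_cached(disc$params, disc_cfg, real_mat,
                                       crop_side_hr, crop_side_hr)
            dff <- disc_forward_cached(disc$params, disc_cfg, gf$out,
                                       crop_side_hr, crop_side_hr)
            real_sc[i] <- dfr$score; fake_sc[i] <- dff$score
            d_caches_real[[i]] <- dfr$caches; d_caches_fake[[i]] <- dff$caches
          }
          l_d <- hinge_d_loss(real_sc, fake_sc)
          for (i in seq_len(B)) {
            dr <- if (real_sc[i] < 1) -1 / B else 0
            df <- if (fake_sc[i] > -1) 1 / B else 0
            if (dr != 0) {
              d_grads <- grads_add(d_grads,
                                   disc_backward(d_caches_real[[i]], dr)$grads)
            }
            if (df != 0) {
              d_grads <- grads_add(d_grads,
                                   disc_backward(d_caches_fake[[i]], df)$grads)
            }
          }
          if (!is.null(d_grads)) {
            upd <- adam_step(disc$params, d_grads, ad_d, lr_now,
                             cfg$beta1, cfg$beta2)
            disc$params <- upd$params; ad_d <- upd$state
          }
        }
      }

      # generator step with fresh scores
      g_grads <- NULL
      fake_sc <- rep(NA_real_, B)
      psnrs <- numeric(B)
      for (i in seq_len(B)) {
        gf <- gen_forward_cached(gen$params, gen_cfg,
                                 feat_to_mat(ups[[i]]$pixels),
                                 crop_side_hr, crop_side_hr)
        xhat_unit <- mat_to_feat(gf$out, gen_cfg$channels,
                                 crop_side_hr, crop_side_hr)
        x_unit <- crops[[i]]$hr$pixels / 255
        psnrs[i] <- per_sample_psnr(sr_image(xhat_unit * 255, "byte"),
                                    crops[[i]]$hr, cfg$loss)
        d_out <- NULL
        if (use_adv) {
          dff <- disc_forward_cached(disc$params, disc_cfg, gf$out,
                                     crop_side_hr, crop_side_hr)
          fake_sc[i] <- dff$score
          if (mode != "psnr_only") {
            adv_back <- disc_backward(dff$caches, -1 / B)
            d_out <- adv_back$dIn
          }
        }
        if (mode %in% c("hybrid", "psnr_only")) {
          gpsnr <- psnr_loss_grad_unit(xhat_unit, x_unit, cfg$loss, B)
          gpsnr_mat <- feat_to_mat(gpsnr)
          lam <- if (mode == "hybrid") cfg$loss$lambda_psnr else 1
          d_out <- if (is.null(d_out)) lam * gpsnr_mat else
            d_out + lam * gpsnr_mat
        }
        g_grads <- grads_add(g_grads, gen_backward(gf$caches, d_out))
      }
      upd <- adam_step(gen$params, g_grads, ad_g, lr_now,
                       cfg$beta1, cfg$beta2)
      gen$params <- upd$params; ad_g <- upd$state

      l_psnr <- -mean(psnrs)
      l_adv <- if (use_adv) adv_g_loss(fake_sc) else NA_real_
      l_g <- switch(mode,
                    hybrid = l_adv + cfg$loss$lambda_psnr * l_psnr,
                    psnr_only = l_psnr,
                    adv_only = l_adv)
      gstep <- gstep + 1L
      step_rows[[gstep]] <- data.frame(step = gstep, epoch = epoch,
                                       l_d = l_d, l_adv_g = l_adv,
                                       l_psnr = l_psnr, l_g = l_g,
                                       learning_rate = lr_now)
    }
    er <- do.call(rbind, step_rows[(gstep - steps_per_epoch + 1L):gstep])
    epoch_rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, l_d = mean(er$l_d), l_adv_g = mean(er$l_adv_g),
      l_psnr = mean(er$l_psnr), l_g = mean(er$l_g),
      learning_rate = lr_now, wall_clock = as.numeric(Sys.time()))
    maybe_checkpoint(epoch + 1L)
  }
  log <- list(epochs = if (length(epoch_rows)) do.call(rbind, epoch_rows)
              else empty_epoch_log(),
              steps = if (length(step_rows)) do.call(rbind, step_rows)
              else empty_step_log())
  if (cfg$epochs == 0L) maybe_checkpoint(0L)
  list(generator = gen, discriminator = disc, log = log)
}

empty_epoch_log <- function() {
  data.frame(epoch = integer(), l_d = numeric(), l_adv_g = numeric(),
             l_psnr = numeric(), l_g = numeric(), learning_rate = numeric(),
             wall_clock = numeric())
}

empty_step_log <- function() {
  data.frame(step = integer(), epoch = integer(), l_d = numeric(),
             l_adv_g = numeric(), l_psnr = numeric(), l_g = numeric(),
             learning_rate = numeric())
}

#' Save / load a model checkpoint
#'
#' A single serialized archive holding both networks' parameters and a
#' versioned manifest of their configurations, so [infer] can rebuild the
#' models without further flags.
#'
#' @param path checkpoint file path (`.rds`).
#' @param generator,discriminator models from [init_generator] /
#'   [init_discriminator] (discriminator may be `NULL`).
#' @param train_cfg optional [train_config] stored for provenance.
#' @export
save_checkpoint <- function(path, generator, discriminator = NULL,
                            train_cfg = NULL) {
  obj <- list(format = "gtsr-checkpoint", version = 1L,
              manifest = list(generator = unclass(generator$config),
                              discriminator = if (!is.null(discriminator))
                                unclass(discriminator$config)),
              gen_params = generator$params,
              disc_params = if (!is.null(discriminator))
                discriminator$params,
              train_cfg = if (!is.null(train_cfg)) unclass(train_cfg))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a list with `generator`,
#'   `discriminator` (possibly `NULL`) and `train_cfg`.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, "gtsr-checkpoint")) {
    stop("corrupt or unrecognized checkpoint: ", path)
  }
  need <- c("manifest", "gen_params")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop("checkpoint ", path, " is missing fields: ",
         paste(missing, collapse = ", "))
  }
  gcfg <- do.call(gt_unet_config, obj$manifest$generator)
  gen <- structure(list(params = obj$gen_params, config = gcfg),
                   class = "generator_model")
  disc <- NULL
  if (!is.null(obj$disc_params)) {
    dcfg <- do.call(vgg_disc_config, obj$manifest$discriminator)
    disc <- structure(list(params = obj$disc_params, config = dcfg),
                      class = "discriminator_model")
  }
  list(generator = gen, discriminator = disc, train_cfg = obj$train_cfg)
}

#' Tiled full-image inference
#'
#' Splits the LR image into overlapping tiles on the LR grid,
#' super-resolves each with [generator_forward], and blends the HR tiles
#' with linear ramp weights over the overlap region (normalized, so
#' coverage is exact everywhere). A tile covering the whole image reduces
#' to a single forward pass.
#'
#' For purely convolutional (tile-local) models the blend reproduces the
#' single-pass result exactly away from tile edges. Because the bottleneck
#' attention is global, each tile of a model with attention layers sees
#' only its own global context, so tiled and whole-image outputs can
#' differ by more than the seam-blending tolerance; use a tile covering
#' the image when exact single-pass behavior is required and memory
#' allows.
#'
#' @param lr_img an [sr_image] in unit range.
#' @param model a `generator_model` or a checkpoint path.
#' @param tile LR tile side in pixels; `tile * s` must be divisible by
#'   `2^scales`.
#' @param overlap LR overlap between neighboring tiles (`0 <= overlap <
#'   tile`).
#' @return an [sr_image] in unit range, `s` times the input size.
#' @export
infer <- function(lr_img, model, tile = 64L, overlap = 8L) {
  if (is.character(model)) model <- load_checkpoint(model)$generator
  stopifnot_range(lr_img, "unit")
  cfg <- model$config
  s <- cfg$scale_factor
  tile <- as.integer(tile); overlap <- as.integer(overlap)
  if (overlap < 0L || tile <= overlap) stop("need tile > overlap >= 0")
  lh <- img_height(lr_img); lw <- img_width(lr_img)
  if (tile >= lh && tile >= lw) return(generator_forward(lr_img, model))
  tile <- min(tile, lh, lw)
  if ((tile * s) %% 2^cfg$scales != 0L) {
    stop("tile * s must be divisible by 2^scales = ", 2^cfg$scales)
  }
  starts <- function(nn) {
    if (tile >= nn) return(1L)
    st <- seq.int(1L, nn - tile + 1L, by = tile - overlap)
    if (st[length(st)] != nn - tile + 1L) st <- c(st, nn - tile + 1L)
    st
  }
  th <- tile * s
  ramp <- pmin(pmin(seq_len(th), th + 1L - seq_len(th)) /
                 max(1L, overlap * s), 1)
  wt <- outer(ramp, ramp)
  ch <- img_channels(lr_img)
  num <- array(0, dim = c(ch, lh * s, lw * s))
  den <- matrix(0, lh * s, lw * s)
  for (r0 in starts(lh)) {
    for (c0 in starts(lw)) {
      sub <- sr_image(lr_img$pixels[, r0:(r0 + tile - 1L),
                                    c0:(c0 + tile - 1L), drop = FALSE],
                      range = "unit")
      out <- generator_forward(sub, model)
      hr0 <- (r0 - 1L) * s; hc0 <- (c0 - 1L) * s
      rows <- (hr0 + 1L):(hr0 + th); cols <- (hc0 + 1L):(hc0 + th)
      for (cc in seq_len(ch)) {
        num[cc, rows, cols] <- num[cc, rows, cols] + out$pixels[cc, , ] * wt
      }
      den[rows, cols] <- den[rows, cols] + wt
    }
  }
  for (cc in seq_len(ch)) num[cc, , ] <- num[cc, , ] / den
  sr_image(num, range = "unit")
}

#' Serialize / restore a training log
#'
#' Full-precision JSON so the log round-trips losslessly.
#'
#' @param log the `log` element returned by [train].
#' @param path output/input path (`.json`).
#' @export
save_training_log <- function(log, path) {
  jsonlite::write_json(log, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname save_training_log
#' @export
read_training_log <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, as.data.frame)
}

#' Plot the training loss curves
#'
#' Per-epoch generator/discriminator loss components against the epoch
#' index (the training-curve diagnostic for the hybrid objective).
#' Requires ggplot2.
#'
#' @param log the `log` element returned by [train].
#' @return a ggplot object.
#' @export
plot_training_log <- function(log) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_training_log requires the ggplot2 package")
  }
  df <- log$epochs
  long <- do.call(rbind, lapply(c("l_d", "l_adv_g", "l_psnr", "l_g"),
                                function(nm) {
    data.frame(epoch = df$epoch, loss = nm, value = df[[nm]])
  }))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
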