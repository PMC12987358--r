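test_that("cosine schedule hits its endpoints and midpoint exactly", {
  cfg <- train_config(epochs = 801L)
  expect_equal(cosine_lr(0, cfg), 1e-4)
  expect_equal(cosine_lr(800, cfg), 1e-5)
  expect_equal(cosine_lr(400, cfg), 5.5e-5)  # cos = 0 at the midpoint
  # monotone non-increasing across the whole schedule
  lrs <- cosine_lr(0:800, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(cosine_lr(801, cfg), "epoch")
  expect_error(cosine_lr(-1, cfg), "epoch")
})

test_that("zero-epoch training returns initialized models and an empty log", {
  cfg <- synthetic_fundus_config(size = 32, seed = 60)
  ds <- make_fixture_dataset(2, cfg, s = 4)
  tc <- train_config(epochs = 0L, batch_size = 1L, crop_hr = 16L, seed = 1L)
  fit <- train(ds, tc, tiny_gen_cfg(scale_factor = 4L, scales = 2L),
               tiny_disc_cfg(16L))
  expect_s3_class(fit$generator, "generator_model")
  expect_equal(nrow(fit$log$epochs), 0)
  expect_equal(nrow(fit$log$steps), 0)
})

test_that("training is bitwise deterministic under a fixed seed", {
  cfg <- synthetic_fundus_config(size = 32, seed = 61)
  ds <- make_fixture_dataset(3, cfg, s = 4)
  gcfg <- tiny_gen_cfg(scale_factor = 4L, scales = 2L)
  tc <- train_config(epochs = 2L, batch_size = 2L, lr_init = 1e-3,
                     lr_final = 1e-4, crop_hr = 16L, seed = 7L)
  fit1 <- train(ds, tc, gcfg, tiny_disc_cfg(16L))
  fit2 <- train(ds, tc, gcfg, tiny_disc_cfg(16L))
  f1 <- fit1$log$epochs; f2 <- fit2$log$epochs
  f1$wall_clock <- NULL; f2$wall_clock <- NULL
  expect_identical(f1, f2)
  expect_identical(fit1$generator$params, fit2$generator$params)
  # a different seed takes a different trajectory
  tc2 <- tc; tc2$seed <- 8L
  fit3 <- train(ds, tc2, gcfg, tiny_disc_cfg(16L))
  expect_false(identical(fit1$generator$params, fit3$generator$params))
})

test_that("training validates configuration consistency up front", {
  cfg <- synthetic_fundus_config(size = 32, seed = 62)
  ds <- make_fixture_dataset(2, cfg, s = 4)
  gcfg <- tiny_gen_cfg(scale_factor = 4L, scales = 2L)
  expect_error(train(ds, train_config(crop_hr = 18L), gcfg), "divisible")
  expect_error(train(ds, train_config(crop_hr = 16L), gcfg,
                     tiny_disc_cfg(32L)), "input_side")
  expect_error(train(list(), train_config(), gcfg), "no training samples")
  gcfg2 <- tiny_gen_cfg(scale_factor = 8L, scales = 2L)
  expect_error(train(ds, train_config(crop_hr = 16L), gcfg2), "match")
})

test_that("per-epoch records follow completed epochs and round-trip", {
  cfg <- synthetic_fundus_config(size = 32, seed = 63)
  ds <- make_fixture_dataset(2, cfg, s = 4)
  tc <- train_config(epochs = 3L, batch_size = 2L, crop_hr = 16L, seed = 2L,
                     lr_init = 1e-3, lr_final = 1e-4)
  fit <- train(ds, tc, tiny_gen_cfg(scale_factor = 4L, scales = 2L),
               tiny_disc_cfg(16L))
  expect_equal(nrow(fit$log$epochs), 3)
  expect_equal(fit$log$epochs$epoch, 0:2)
  expect_equal(nrow(fit$log$steps), 3)  # ceil(2/2) = 1 step per epoch
  expect_equal(fit$log$epochs$learning_rate, cosine_lr(0:2, tc))
  path <- withr::local_tempfile(fileext = ".json")
  save_training_log(fit$log, path)
  back <- read_training_log(path)
  expect_equal(back$epochs, fit$log$epochs)
  expect_equal(back$steps, fit$log$steps)
})

test_that("checkpoints rebuild models that reproduce outputs exactly", {
  set.seed(64)
  gcfg <- tiny_gen_cfg(scale_factor = 4L, scales = 2L)
  gen <- init_generator(gcfg)
  gen$params[["final.W"]][] <- rnorm(length(gen$params[["final.W"]]),
                                     sd = 0.05)
  disc <- init_discriminator(tiny_disc_cfg(16L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(path, gen, disc, train_config())
  back <- load_checkpoint(path)
  y <- random_image(8, 8, range = "unit", seed = 65)
  expect_identical(generator_forward(y, back$generator)$pixels,
                   generator_forward(y, gen)$pixels)
  expect_identical(back$discriminator$params, disc$params)
  # corrupt checkpoints are refused with a clear error
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), bad)
  expect_error(load_checkpoint(bad), "corrupt")
})

test_that("tiled inference agrees with a single forward pass", {
  set.seed(66)
  gcfg <- tiny_gen_cfg(scale_factor = 2L, scales = 2L)
  gen <- init_generator(gcfg)
  gen$params[["final.W"]][] <- rnorm(length(gen$params[["final.W"]]),
                                     sd = 0.05)
  y <- random_image(64, 64, range = "unit", seed = 67)
  whole <- generator_forward(y, gen)
  # a tile covering the image is exactly the single pass
  expect_identical(infer(y, gen, tile = 64L, overlap = 8L)$pixels,
                   whole$pixels)
  tiled <- infer(y, gen, tile = 32L, overlap = 8L)
  expect_equal(dim(tiled$pixels), dim(whole$pixels))
  # for a tile-local model (zero residual: per-tile bicubic upsampling)
  # the blend is exact away from tile edges and bounded at the seams
  gen0 <- init_generator(gcfg)
  whole0 <- generator_forward(y, gen0)
  tiled0 <- infer(y, gen0, tile = 32L, overlap = 8L)
  D <- abs(tiled0$pixels[1, , ] - whole0$pixels[1, , ])
  edges <- c(1, 49, 64, 65, 112, 128)  # HR coords of tile starts/ends
  dist_edge <- function(i) min(abs(i - edges))
  far <- outer(1:128, 1:128, Vectorize(function(r, c) {
    min(dist_edge(r), dist_edge(c)) > 4
  }))
  expect_lt(max(D[far]), 1e-9)
  expect_lt(max(D), 0.05)
  # constant input through a zero-residual network stays constant
  const <- sr_image(array(0.5, c(1, 64, 64)), "unit")
  out0 <- infer(const, gen0, tile = 32L, overlap = 8L)
  expect_lt(max(abs(out0$pixels - 0.5)), 1e-9)
  expect_error(infer(y, gen, tile = 8L, overlap = 8L), "overlap")
})

test_that("checkpoints written during training are loadable", {
  cfg <- synthetic_fundus_config(size = 32, seed = 68)
  ds <- make_fixture_dataset(2, cfg, s = 4)
  dir <- withr::local_tempdir()
  tc <- train_config(epochs = 2L, batch_size = 2L, crop_hr = 16L, seed = 3L,
                     lr_init = 1e-3, lr_final = 1e-4, checkpoint_every = 1L)
  fit <- train(ds, tc, tiny_gen_cfg(scale_factor = 4L, scales = 2L),
               tiny_disc_cfg(16L), checkpoint_dir = dir)
  files <- list.files(dir, pattern = "^ckpt_epoch")
  expect_gte(length(files), 2)
  back <- load_checkpoint(file.path(dir, sort(files)[length(files)]))
  expect_identical(back$generator$params, fit$generator$params)
})
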