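test_that("degrade produces exact-scale pairs and matches the oracle", {
  hr <- random_image(64, 64, seed = 21)
  pair <- degrade(hr, 8, id = "a")
  expect_equal(dim(pair$lr$pixels)[2:3], c(8L, 8L))
  expect_identical(pair$hr$pixels, hr$pixels)
  # lr is bit-for-bit the pinned bicubic downsample (the LR-consistency
  # ground truth)
  expect_identical(pair$lr$pixels,
                   bicubic_resample(hr, 8, 8)$pixels)
  # ramp image, s = 2, against the direct-convolution oracle
  ramp <- sr_image(matrix(seq(0, 255, length.out = 32 * 32), 32, 32), "byte")
  pr <- degrade(ramp, 2)
  ref <- oracle_bicubic(matrix(ramp$pixels[1, , ], 32, 32), 16, 16)
  expect_lt(max(abs(pr$lr$pixels[1, , ] - ref)), 1e-6)
  # constant stays constant
  pc <- degrade(sr_image(array(42, c(1, 16, 16)), "byte"), 4)
  expect_lt(max(abs(pc$lr$pixels - 42)), 1e-9)
})

test_that("degrade refuses non-divisible sizes and bad factors", {
  hr <- random_image(30, 30)
  expect_error(degrade(hr, 8), "not divisible")
  expect_error(degrade(hr, 1), ">= 2")
})

test_that("split_dataset is an 8:2 partition, deterministic under seed", {
  mk <- function(n) lapply(seq_len(n), function(i) {
    structure(list(id = sprintf("s%04d", i)), class = "paired_sample")
  })
  s800 <- split_dataset(mk(800), seed = 3)
  expect_length(s800$train, 640)
  expect_length(s800$test, 160)
  s10 <- split_dataset(mk(10), seed = 3)
  expect_length(s10$train, 8)
  expect_length(s10$test, 2)
  # partition: disjoint, exhaustive
  expect_length(intersect(s10$train, s10$test), 0)
  expect_setequal(c(s10$train, s10$test), sprintf("s%04d", 1:10))
  # same seed reproduces; different seeds permute differently
  expect_identical(split_dataset(mk(10), seed = 3), s10)
  perms <- vapply(1:10, function(sd) {
    paste(split_dataset(mk(10), seed = sd)$train, collapse = ",")
  }, character(1))
  expect_gt(length(unique(perms)), 1)
  expect_error(split_dataset(mk(4)), "at least 5")
})

test_that("degenerate fundus config yields background, field and disc only", {
  cfg <- synthetic_fundus_config(size = 64, n_vessel_roots = 0,
                                 noise_sigma = 0, seed = 5)
  img <- make_synthetic_fundus(cfg)
  px <- img$pixels
  expect_true(all(px >= 0 & px <= 255))
  # plateau values: away from anti-aliased edges the image takes at most
  # three distinct levels (surround < field < disc)
  lvl <- sort(unique(round(as.numeric(px), 6)))
  plateaus <- lvl[vapply(lvl, function(v) mean(abs(px - v) < 1e-9) > 0.01,
                         logical(1))]
  expect_lte(length(plateaus), 3)
  expect_gte(length(plateaus), 2)
  expect_true(max(px) > mean(px))  # bright disc over darker field
})

test_that("fundus generation is a pure function of its config", {
  cfg <- synthetic_fundus_config(size = 64, seed = 9)
  a <- make_synthetic_fundus(cfg)
  b <- make_synthetic_fundus(cfg)
  expect_identical(a$pixels, b$pixels)
  cfg2 <- synthetic_fundus_config(size = 64, seed = 10)
  expect_false(identical(make_synthetic_fundus(cfg2)$pixels, a$pixels))
})

test_that("synthetic fundus carries genuine high-frequency content", {
  cfg <- synthetic_fundus_config(size = 256, n_vessel_roots = 4,
                                 branch_depth = 5, seed = 2)
  img <- make_synthetic_fundus(cfg)
  lap <- function(m) {
    k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)
    oracle_filter3(m, k)
  }
  down <- bicubic_resample(img, 32, 32)
  rec <- bicubic_resample(down, 256, 256)
  e_img <- sum(lap(matrix(img$pixels[1, , ], 256, 256))^2)
  e_rec <- sum(lap(matrix(rec$pixels[1, , ], 256, 256))^2)
  expect_gt(e_img, e_rec)
})

test_that("fixture datasets are reproducible and LR-consistent", {
  cfg <- synthetic_fundus_config(size = 64, seed = 30)
  ds <- make_fixture_dataset(3, cfg, s = 8)
  expect_length(ds, 3)
  for (p in ds) {
    expect_equal(dim(p$lr$pixels)[2:3], c(8L, 8L))
    expect_equal(dim(p$hr$pixels)[2:3], c(64L, 64L))
    expect_identical(p$lr$pixels, bicubic_resample(p$hr, 8, 8)$pixels)
  }
  ds2 <- make_fixture_dataset(1, cfg, s = 8)
  expect_identical(ds2[[1]]$hr$pixels, ds[[1]]$hr$pixels)
  expect_error(make_fixture_dataset(2, synthetic_fundus_config(size = 60),
                                    s = 8), "divisible")
})

test_that("datasets round-trip through the on-disk layout", {
  cfg <- synthetic_fundus_config(size = 32, seed = 40)
  ds <- make_fixture_dataset(5, cfg, s = 4)
  split <- split_dataset(ds, seed = 1)
  root <- withr::local_tempdir()
  write_dataset(ds, root, split = split)
  expect_true(file.exists(file.path(root, "hr", "synth_001.png")))
  expect_true(file.exists(file.path(root, "lr", "synth_001.png")))
  meta <- jsonlite::read_json(file.path(root, "split.json"),
                              simplifyVector = TRUE)
  expect_setequal(c(meta$train, meta$test),
                  vapply(ds, function(s) s$id, character(1)))
  hr_back <- read_image(file.path(root, "hr", "synth_001.png"))
  expect_identical(hr_back$pixels, round(ds[[1]]$hr$pixels))
})
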