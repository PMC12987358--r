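psnr_cap <- 10 * log10(255^2 / 1e-4)

test_that("SSIM self-similarity, symmetry and oracle agreement", {
  img <- random_image(16, 16, seed = 50)
  expect_equal(metric_ssim(img, img), 1)
  # structured pattern vs noisy copy against the sliding-window oracle
  patt <- sr_image(outer(1:16, 1:16, function(r, c) {
    127 + 100 * sin(r / 2) * cos(c / 3)
  }), "byte")
  noisy <- sr_image(patt$pixels + withr::with_seed(51, {
    array(rnorm(256, sd = 12), c(1, 16, 16))
  }), "byte")
  expect_equal(metric_ssim(patt, noisy),
               oracle_ssim(matrix(patt$pixels[1, , ], 16, 16),
                           matrix(noisy$pixels[1, , ], 16, 16)),
               tolerance = 1e-6)
  # symmetry
  expect_equal(metric_ssim(patt, noisy), metric_ssim(noisy, patt),
               tolerance = 1e-9)
  # inversion breaks similarity for non-constant images
  inv <- sr_image(255 - patt$pixels, "byte")
  expect_lt(metric_ssim(patt, inv), 1)
  expect_error(metric_ssim(random_image(8, 8), random_image(8, 8)),
               "window")
})

test_that("Sobel and Laplacian filters match the loop oracle and kill constants", {
  set.seed(52)
  m <- matrix(rnorm(64, 100, 40), 8, 8)
  for (k in list(gtsr:::sobel_x_kernel(), gtsr:::sobel_y_kernel(),
                 gtsr:::laplacian_kernel())) {
    expect_lt(max(abs(gtsr:::filter3_mirror(m, k) - oracle_filter3(m, k))),
              1e-9)
    expect_equal(gtsr:::filter3_mirror(matrix(7, 6, 6), k), matrix(0, 6, 6))
  }
})

test_that("gradient and high-frequency errors vanish on LR-identical pairs", {
  hr <- make_synthetic_fundus(synthetic_fundus_config(size = 64, seed = 53))
  pair <- degrade(hr, 4)
  # xhat whose downsample IS the LR input
  expect_equal(grad_cons(pair$hr, pair$lr, 4), 0, tolerance = 1e-12)
  expect_equal(hf_err(pair$hr, pair$lr, 4), 0, tolerance = 1e-12)
  # constant offsets are annihilated by the zero-sum kernels (s = 1 so the
  # offset survives the downsampler untouched)
  off <- sr_image(pair$lr$pixels + 11, "byte")
  expect_equal(grad_cons(off, pair$lr, 1), 0, tolerance = 1e-12)
  expect_equal(hf_err(off, pair$lr, 1), 0, tolerance = 1e-12)
})

test_that("the Laplacian annihilates affine ramps away from borders", {
  ramp <- outer(1:12, 1:12, function(r, c) 3 * r + 5 * c + 10)
  resp <- gtsr:::filter3_mirror(ramp, gtsr:::laplacian_kernel())
  expect_lt(max(abs(resp[2:11, 2:11])), 1e-9)  # interior only
  expect_gt(max(abs(resp)), 0)  # mirror borders do respond
})

test_that("LR consistency caps exactly on self-consistent constructions", {
  hr <- make_synthetic_fundus(synthetic_fundus_config(size = 96, seed = 54))
  y <- bicubic_resample(hr, 24, 24)  # define y := Down(xhat)
  lrc <- lr_consistency(hr, y, 4)
  expect_equal(lrc$lr_psnr, psnr_cap)
  expect_equal(lrc$lr_ssim, 1)
  # bicubic upsample of y is not exactly LR-consistent: finite, high,
  # below the cap
  up <- bicubic_resample(y, 96, 96)
  lrc_up <- lr_consistency(up, y, 4)
  expect_lt(lrc_up$lr_psnr, psnr_cap)
  expect_gt(lrc_up$lr_psnr, 25)
  # the cap is hit iff Down(xhat) == y: any perturbation drops it
  pert <- sr_image(hr$pixels + 2, "byte")
  expect_lt(lr_consistency(pert, y, 4)$lr_psnr, psnr_cap)
  # s = 1 reduces to the plain metrics
  expect_equal(lr_consistency(y, y, 1)$lr_psnr, metric_psnr(y, y))
  expect_error(lr_consistency(hr, y, 3), "exactly")
})

test_that("evaluate_pairs aggregates per-sample reports", {
  cfg <- synthetic_fundus_config(size = 64, seed = 55)
  ds <- make_fixture_dataset(2, cfg, s = 4)
  # perfect outputs: PSNR at the cap, SSIM 1, LR metrics self-consistent
  perfect <- lapply(ds, function(p) p$hr)
  rep <- evaluate_pairs(ds, perfect)
  expect_equal(nrow(rep$per_sample), 2)
  expect_equal(unname(rep$mean["psnr"]), psnr_cap)
  expect_equal(unname(rep$mean["ssim"]), 1)
  expect_equal(unname(rep$mean["lr_psnr"]), psnr_cap)
  expect_equal(unname(rep$mean["grad_cons"]), 0, tolerance = 1e-12)
  expect_error(evaluate_pairs(list(), list()), "empty")
  expect_error(evaluate_pairs(ds, perfect[1]), "misaligned")
})

test_that("the bicubic baseline reproduces its frozen reference row", {
  cfg <- synthetic_fundus_config(size = 128, seed = 56)
  ds <- make_fixture_dataset(1, cfg, s = 8)
  up <- bicubic_resample(ds[[1]]$lr, 128, 128)
  up$pixels <- pmin(pmax(up$pixels, 0), 255)
  rep <- evaluate_pairs(ds, list(up))
  # frozen regression values for the pinned resampler + metric dialects
  frozen <- .gtsr_baseline_row
  for (nm in names(frozen)) {
    expect_equal(unname(rep$mean[nm]), frozen[[nm]], tolerance = 1e-6,
                 label = nm)
  }
})
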