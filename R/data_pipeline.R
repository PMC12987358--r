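#' Build a supervised LR/HR pair by bicubic degradation
#'
#' The degradation model: the low-resolution observation is the bicubic
#' downsampling of the high-resolution image by an integer scale factor
#' `s`, using the package's pinned antialiased Catmull-Rom resampler
#' ([bicubic_resample]). The HR image is stored unmodified; no implicit
#' cropping is performed, so the HR sides must be divisible by `s`.
#'
#' @param hr an [sr_image], the high-resolution ground truth.
#' @param s integer scale factor >= 2.
#' @param id sample identifier string.
#' @return a `paired_sample`: list with `lr`, `hr` ([sr_image]s), `id`, `s`.
#' @export
degrade <- function(hr, s, id = "sample") {
  if (!inherits(hr, "sr_image")) stop("expected an sr_image")
  s <- as.integer(s)
  if (is.na(s) || s < 2L) stop("scale factor must be an integer >= 2")
  h <- img_height(hr); w <- img_width(hr)
  if (h %% s != 0L || w %% s != 0L) {
    stop("HR size ", h, "x", w, " is not divisible by scale factor ", s,
         " (no implicit cropping)")
  }
  lr <- bicubic_resample(hr, h %/% s, w %/% s)
  structure(list(lr = lr, hr = hr, id = as.character(id), s = s),
            class = "paired_sample")
}

#' Split paired samples 8:2 into train and test sets
#'
#' Deterministic shuffle under `seed`; the test set takes `floor(n / 5)`
#' samples and the remainder (including any rounding remainder) goes to the
#' training set, giving an 8:2 ratio.
#'
#' @param samples list of `paired_sample` objects (at least 5).
#' @param seed integer seed for the shuffle.
#' @return a `dataset_split`: list with character vectors `train`, `test`
#'   and the `seed`.
#' @export
split_dataset <- function(samples, seed = 0L) {
  if (length(samples) < 5L) {
    stop("need at least 5 samples to split 8:2, got ", length(samples))
  }
  ids <- vapply(samples, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  perm <- withr::with_seed(as.integer(seed), sample.int(length(ids)))
  n_test <- floor(length(ids) / 5)
  shuffled <- ids[perm]
  structure(list(train = shuffled[seq_len(length(ids) - n_test)],
                 test = shuffled[seq.int(length(ids) - n_test + 1L, length(ids))],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Synthetic fundus image configuration
#'
#' Parameters of the synthetic retinal fundus generator used for all test
#' and demonstration fixtures: a near-black surround, a dark circular
#' retinal field, a brighter optic disc, recursively branching vessel trees
#' drawn as anti-aliased dark curves, and additive Gaussian sensor noise.
#'
#' @param size side length in pixels.
#' @param n_vessel_roots number of vessel trees rooted at the disc margin.
#' @param branch_depth binary branching generations per tree.
#' @param vessel_width0 root vessel width in pixels.
#' @param width_decay multiplicative width decay per branch generation,
#'   in (0, 1).
#' @param disc_radius_frac optic-disc radius as a fraction of `size / 2`.
#' @param noise_sigma additive Gaussian noise s.d. on the byte scale.
#' @param seed integer seed; the generated image is a pure function of the
#'   configuration.
#' @return a `fundus_config` list.
#' @export
synthetic_fundus_config <- function(size = 256L, n_vessel_roots = 4L,
                                    branch_depth = 5L, vessel_width0 = 4,
                                    width_decay = 0.8,
                                    disc_radius_frac = 0.16,
                                    noise_sigma = 3, seed = 0L) {
  size <- as.integer(size)
  if (is.na(size) || size < 16L) stop("size must be an integer >= 16")
  if (n_vessel_roots < 0L) stop("n_vessel_roots must be >= 0")
  if (branch_depth < 1L) stop("branch_depth must be >= 1")
  if (vessel_width0 <= 0) stop("vessel_width0 must be positive")
  if (width_decay <= 0 || width_decay >= 1) stop("width_decay must be in (0,1)")
  if (disc_radius_frac <= 0 || disc_radius_frac >= 1) {
    stop("disc_radius_frac must be in (0,1)")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(size = size, n_vessel_roots = as.integer(n_vessel_roots),
                 branch_depth = as.integer(branch_depth),
                 vessel_width0 = vessel_width0, width_decay = width_decay,
                 disc_radius_frac = disc_radius_frac,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fundus_config")
}

# anti-aliased filled circle coverage: 1 inside, 0 outside, linear ramp
# across the one-pixel boundary band
circle_coverage <- function(size, cx, cy, r) {
  x <- matrix(rep(seq_len(size), each = size), size, size)   # col index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  pmin(pmax(r - d + 0.5, 0), 1)
}

# stamp an anti-aliased thick polyline point into the coverage matrix
stamp_points <- function(cov, xs, ys, width, size) {
  r <- width / 2
  win <- ceiling(r + 1)
  for (k in seq_along(xs)) {
    x <- xs[k]; y <- ys[k]
    r0 <- max(1L, floor(y) - win); r1 <- min(size, ceiling(y) + win)
    c0 <- max(1L, floor(x) - win); c1 <- min(size, ceiling(x) + win)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d <- sqrt(outer((rr - y)^2, (cc - x)^2, `+`))
    c_new <- pmin(pmax(r - d + 0.5, 0), 1)
    cov[rr, cc] <- pmax(cov[rr, cc], c_new)
  }
  cov
}

# quadratic Bezier sample points between p0 and p2 with control p1
bezier_points <- function(p0, p1, p2, step = 0.5) {
  chord <- sqrt(sum((p2 - p0)^2))
  n <- max(2L, ceiling(chord / step) + 1L)
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  list(x = x, y = y)
}

#' Generate a synthetic fundus-like image
#'
#' Deterministic under the configuration seed. The image (grayscale, byte
#' range) is composed of a near-black surround, a dark circular retinal
#' field, a filled optic disc of radius `disc_radius_frac * size / 2`
#' brighter than the field, `n_vessel_roots` recursive binary vessel trees
#' drawn as anti-aliased dark quadratic-Bezier curves whose width decays by
#' `width_decay` per generation down to `branch_depth`, and additive
#' Gaussian noise clamped to the byte range. Branch angles are drawn
#' uniformly from \[15, 50\] degrees.
#'
#' @param cfg a [synthetic_fundus_config].
#' @return a single-channel [sr_image] in byte range.
#' @export
make_synthetic_fundus <- function(cfg) {
  if (!inherits(cfg, "fundus_config")) stop("expected a fundus_config")
  withr::with_seed(cfg$seed, {
    size <- cfg$size
    bg <- 8; field_val <- 110; disc_val <- 200; vessel_depth_val <- 75
    centre <- (size + 1) / 2
    field_r <- 0.47 * size
    field <- circle_coverage(size, centre, centre, field_r)
    disc_r <- cfg$disc_radius_frac * size / 2
    disc_angle <- stats::runif(1, -pi / 6, pi / 6)
    disc_cx <- centre + 0.55 * field_r * cos(disc_angle)
    disc_cy <- centre + 0.55 * field_r * sin(disc_angle)
    disc <- circle_coverage(size, disc_cx, disc_cy, disc_r)

    vessels <- matrix(0, size, size)
    if (cfg$n_vessel_roots > 0L) {
      # each root starts at the disc margin heading away from the disc
      root_angles <- stats::runif(cfg$n_vessel_roots, 0, 2 * pi)
      seg_len0 <- 0.16 * size
      draw_branch <- function(p0, angle, len, width, depth) {
        p2 <- p0 + len * c(cos(angle), sin(angle))
        # control point: midpoint displaced perpendicular for curvature
        mid <- (p0 + p2) / 2
        perp <- c(-sin(angle), cos(angle))
        p1 <- mid + stats::runif(1, -0.25, 0.25) * len * perp
        pts <- bezier_points(p0, p1, p2, step = 0.5)
        vessels <<- stamp_points(vessels, pts$x, pts$y, width, size)
        if (depth < cfg$branch_depth) {
          spread <- stats::runif(2, 15, 50) * pi / 180
          draw_branch(p2, angle - spread[1], len * 0.8,
                      width * cfg$width_decay, depth + 1L)
          draw_branch(p2, angle + spread[2], len * 0.8,
                      width * cfg$width_decay, depth + 1L)
        }
      }
      for (a in root_angles) {
        p0 <- c(disc_cx + disc_r * cos(a), disc_cy + disc_r * sin(a))
        draw_branch(p0, a, seg_len0, cfg$vessel_width0, 1L)
      }
    }

    img <- bg + (field_val - bg) * field
    img <- img + (disc_val - field_val) * disc * field
    img <- img - vessel_depth_val * vessels * field * (1 - disc)
    if (cfg$noise_sigma > 0) {
      img <- img + stats::rnorm(size * size, sd = cfg$noise_sigma)
    }
    img <- pmin(pmax(img, 0), 255)
    sr_image(img, range = "byte")
  })
}

#' Generate a fixture dataset of paired LR/HR samples
#'
#' Draws `n` synthetic fundus images with per-sample seeds `cfg$seed + i - 1`
#' and passes each through [degrade], so every pair satisfies the exact
#' LR-consistency ground truth `lr == Down(hr)`.
#'
#' @param n number of samples (>= 1).
#' @param cfg a [synthetic_fundus_config]; `cfg$size` must be divisible
#'   by `s`.
#' @param s integer scale factor.
#' @return list of `paired_sample`s with ids `"synth_001"`, ...
#' @export
make_fixture_dataset <- function(n, cfg, s = 8L) {
  if (n < 1L) stop("n must be >= 1")
  if (cfg$size %% as.integer(s) != 0L) {
    stop("fixture size ", cfg$size, " is not divisible by scale ", s)
  }
  lapply(seq_len(n), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + i - 1L
    degrade(make_synthetic_fundus(ci), s, id = sprintf("synth_%03d", i))
  })
}

#' Write a paired dataset to disk
#'
#' Layout: `<root>/hr/<id>.png`, `<root>/lr/<id>.png`, `<root>/split.json`.
#'
#' @param samples list of `paired_sample`s.
#' @param root output directory (created if missing).
#' @param split optional `dataset_split` to record alongside the images.
#' @export
write_dataset <- function(samples, root, split = NULL) {
  dir.create(file.path(root, "hr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "lr"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    write_image(s$hr, file.path(root, "hr", paste0(s$id, ".png")))
    write_image(s$lr, file.path(root, "lr", paste0(s$id, ".png")))
  }
  if (!is.null(split)) {
    jsonlite::write_json(list(train = split$train, test = split$test,
                              seed = split$seed),
                         file.path(root, "split.json"), auto_unbox = TRUE)
  }
  invisible(NULL)
}
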