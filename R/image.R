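#' Planar image container
#'
#' `sr_image` is the unit of all I/O, degradation and metric computation in
#' gtsr: a real-valued array indexed `(channel, row, col)` together with a
#' declared value range, either `"byte"` (\[0, 255\], the scale on which PSNR
#' with peak value M = 255 is defined) or `"unit"` (\[0, 1\], the scale the
#' networks operate on).
#'
#' @param pixels numeric array `c(channels, height, width)`, or a plain
#'   `height x width` matrix (promoted to one channel).
#' @param range `"byte"` or `"unit"`.
#' @return an object of class `sr_image`.
#' @examples
#' img <- sr_image(matrix(runif(64), 8, 8), range = "unit")
#' dim(img$pixels)
#' @export
sr_image <- function(pixels, range = c("byte", "unit")) {
  range <- match.arg(range)
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, nrow(pixels), ncol(pixels)))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be a (channel, row, col) array or a matrix")
  }
  d <- dim(pixels)
  if (!d[1] %in% c(1L, 3L)) stop("channels must be 1 or 3, got ", d[1])
  if (d[2] < 1L || d[3] < 1L) stop("image must be at least 1x1")
  if (!is.double(pixels)) storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, range = range), class = "sr_image")
}

#' @export
print.sr_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<sr_image %dx%d, %d channel%s, %s range [%.3g, %.3g]>\n",
              d[2], d[3], d[1], if (d[1] > 1) "s" else "", x$range,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.sr_image <- function(x) dim(x$pixels)

img_height <- function(img) dim(img$pixels)[2]
img_width <- function(img) dim(img$pixels)[3]
img_channels <- function(img) dim(img$pixels)[1]

stopifnot_range <- function(img, range) {
  if (!inherits(img, "sr_image")) stop("expected an sr_image")
  if (img$range != range) {
    stop("expected an image in ", range, " range, got ", img$range)
  }
}

#' Convert between byte and unit value ranges
#'
#' Linear maps by the factor 255. `to_unit` takes a byte-range image to
#' \[0, 1\]; `to_byte` is its exact inverse (up to floating point). Neither
#' clamps.
#'
#' @param img an [sr_image] in the source range.
#' @return an [sr_image] in the target range.
#' @export
to_unit <- function(img) {
  stopifnot_range(img, "byte")
  sr_image(img$pixels / 255, range = "unit")
}

#' @rdname to_unit
#' @export
to_byte <- function(img) {
  stopifnot_range(img, "unit")
  sr_image(img$pixels * 255, range = "byte")
}

#' Read an image file
#'
#' Reads an 8- or 16-bit PNG or TIFF into a byte-range [sr_image].
#' 16-bit samples are rescaled linearly so that the maximum representable
#' value maps to 255. An alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return an [sr_image] in byte range.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image extension '", ext, "' for ", path)
    ),
    error = function(e) stop("failed to read image ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  # readPNG/readTIFF normalize to [0,1] regardless of bit depth
  if (length(dim(arr)) == 2L) {
    px <- array(arr, dim = c(1L, nrow(arr), ncol(arr)))
  } else {
    nc <- dim(arr)[3]
    if (nc %in% c(2L, 4L)) arr <- arr[, , seq_len(nc - 1L), drop = FALSE]
    nc <- dim(arr)[3]
    if (nc == 2L) arr <- arr[, , 1L, drop = FALSE]  # gray+alpha reduced
    px <- aperm(arr, c(3L, 1L, 2L))
  }
  sr_image(px * 255, range = "byte")
}

#' Write an image to an 8-bit PNG
#'
#' Values are clamped to \[0, 255\] and rounded half-to-even before writing.
#' `write_image` then `read_image` is the identity on byte-valued images.
#'
#' @param img an [sr_image] in byte range.
#' @param path output path (`.png`).
#' @export
write_image <- function(img, path) {
  stopifnot_range(img, "byte")
  q <- round(pmin(pmax(img$pixels, 0), 255))
  arr <- if (img_channels(img) == 1L) {
    matrix(q[1L, , ], img_height(img), img_width(img))
  } else {
    aperm(q, c(2L, 3L, 1L))
  }
  ok <- tryCatch({ png::writePNG(arr / 255, target = path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("failed to write image to ", path)
  invisible(NULL)
}

# --- bicubic resampling (Catmull-Rom a = -0.5, antialiased, mirror borders) --

# Catmull-Rom cubic kernel, support [-2, 2]
cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- !i1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# reflect-without-repeat: 0 -> 2, -1 -> 3, n+1 -> n-1
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  ifelse(j >= n, p - j, j) + 1L
}

# n_out x n_in row-stochastic resampling matrix along one axis; when
# downscaling the kernel support is stretched by the scale factor
# (antialiasing), and out-of-range taps fold back by mirror reflection.
resample_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  f <- max(1, scale)
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    x <- (j - 0.5) * scale + 0.5
    taps <- seq.int(ceiling(x - 2 * f), floor(x + 2 * f))
    w <- cubic_kernel((x - taps) / f)
    w <- w / sum(w)
    m <- mirror_index(taps, n_in)
    for (k in seq_along(taps)) W[j, m[k]] <- W[j, m[k]] + w[k]
  }
  W
}

#' Bicubic resampling
#'
#' Separable bicubic resampling with the Catmull-Rom kernel (a = -0.5).
#' When downscaling, the kernel support is stretched by the scale factor so
#' the operator antialiases; borders are handled by mirror reflection
#' (without repeating the edge sample). The kernel weights are normalized per
#' output pixel, so a constant image resamples to the same constant at any
#' size. The output keeps the input's declared value range and is not
#' clamped. This single pinned operator is used both for the degradation
#' model that builds LR/HR training pairs and inside every LR-consistency
#' metric, so exact LR consistency is attainable.
#'
#' @param img an [sr_image].
#' @param out_height,out_width target size in pixels (>= 1).
#' @return an [sr_image] of size `out_height x out_width`.
#' @examples
#' hr <- sr_image(matrix(runif(64 * 64), 64, 64), "unit")
#' lr <- bicubic_resample(hr, 8, 8)
#' @export
bicubic_resample <- function(img, out_height, out_width) {
  if (!inherits(img, "sr_image")) stop("expected an sr_image")
  if (out_height < 1 || out_width < 1) {
    stop("target size must be >= 1, got ", out_height, "x", out_width)
  }
  h <- img_height(img); w <- img_width(img); ch <- img_channels(img)
  Wr <- resample_matrix(h, as.integer(out_height))
  Wc <- resample_matrix(w, as.integer(out_width))
  out <- array(0, dim = c(ch, as.integer(out_height), as.integer(out_width)))
  for (c in seq_len(ch)) {
    out[c, , ] <- Wr %*% img$pixels[c, , ] %*% t(Wc)
  }
  sr_image(out, range = img$range)
}
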