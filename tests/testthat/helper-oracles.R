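# Independent reference implementations used as oracles. These are written
# as literal, loop-based transcriptions of the definitions and share no code
# with the package internals they check.

# direct-convolution bicubic resampling: explicitly builds the stretched
# Catmull-Rom kernel and walks a conceptually mirror-padded input, pixel by
# pixel, normalizing by the 2D weight sum
oracle_bicubic <- function(px, oh, ow) {
  h <- nrow(px); w <- ncol(px)
  cub <- function(t, a = -0.5) {
    at <- abs(t)
    if (at <= 1) (a + 2) * at^3 - (a + 3) * at^2 + 1
    else if (at < 2) a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a
    else 0
  }
  refl <- function(i, n) {
    if (n == 1) return(1)
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  fr <- max(1, h / oh); fc <- max(1, w / ow)
  out <- matrix(0, oh, ow)
  for (r in seq_len(oh)) {
    yy <- (r - 0.5) * h / oh + 0.5
    for (c in seq_len(ow)) {
      xx <- (c - 0.5) * w / ow + 0.5
      acc <- 0; wsum <- 0
      for (i in ceiling(yy - 2 * fr):floor(yy + 2 * fr)) {
        wi <- cub((yy - i) / fr)
        for (j in ceiling(xx - 2 * fc):floor(xx + 2 * fc)) {
          wv <- wi * cub((xx - j) / fc)
          acc <- acc + wv * px[refl(i, h), refl(j, w)]
          wsum <- wsum + wv
        }
      }
      out[r, c] <- acc / wsum
    }
  }
  out
}

# dense-loop multi-head self-attention: per-token score loops, explicit
# softmax, explicit weighted value sums
oracle_msa <- function(Z, p) {
  n <- nrow(Z); d <- ncol(Z); M <- p$heads; dm <- d / M
  H <- matrix(0, n, d)
  for (m in seq_len(M)) {
    cols <- ((m - 1) * dm + 1):(m * dm)
    Q <- Z %*% p$Wq[, cols]; K <- Z %*% p$Wk[, cols]; V <- Z %*% p$Wv[, cols]
    for (i in seq_len(n)) {
      s <- numeric(n)
      for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dm)
      a <- exp(s - max(s)); a <- a / sum(a)
      for (j in seq_len(n)) H[i, cols] <- H[i, cols] + a[j] * V[j, ]
    }
  }
  H %*% p$Wo
}

# sliding-window SSIM: explicit 11x11 Gaussian-weighted moments at every
# valid window position
oracle_ssim <- function(a, b) {
  t <- seq(-5, 5)
  g1 <- exp(-t^2 / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  h <- nrow(a); w <- ncol(a)
  vals <- c()
  for (r in 1:(h - 10)) {
    for (c in 1:(w - 10)) {
      wa <- a[r:(r + 10), c:(c + 10)]
      wb <- b[r:(r + 10), c:(c + 10)]
      mu_a <- sum(G * wa); mu_b <- sum(G * wb)
      va <- sum(G * wa^2) - mu_a^2
      vb <- sum(G * wb^2) - mu_b^2
      cab <- sum(G * wa * wb) - mu_a * mu_b
      vals <- c(vals, ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
                  ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

# plain double-loop 3x3 cross-correlation with mirror borders
oracle_filter3 <- function(m, kernel) {
  h <- nrow(m); w <- ncol(m)
  refl <- function(i, n) {
    if (i < 1) return(2 - i)
    if (i > n) return(2 * n - i)
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          acc <- acc + kernel[di + 2, dj + 2] * m[refl(r + di, h),
                                                  refl(c + dj, w)]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# central finite differences of a scalar function of an array
fd_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}
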