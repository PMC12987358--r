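# Internal neural-network primitives.
#
# Feature maps are stored as an N x C matrix (N = h*w spatial positions in
# row-major order, position p = (r-1)*w + c; C channels). 3x3 convolutions
# are evaluated by im2col + one BLAS gemm; their backward passes are exact
# (weight gradient by crossprod, input gradient by scatter-add through the
# same mirror-pad index tables). All parameters live in flat named lists of
# numeric arrays so Adam and finite-difference checks can treat them
# uniformly.

.gtsr_idx_cache <- new.env(parent = emptyenv())

# index tables for mirror-padded 3x3 convolution on an h x w grid:
# $nbr: list of 9 integer vectors (offset-major, di then dj in -1:1 order),
#       nbr[[k]][p] = row-major index of the k-th neighbor of position p
# $sel2: row-major positions with odd row and odd col (stride-2 output)
conv_idx <- function(h, w) {
  key <- paste0(h, "x", w)
  hit <- .gtsr_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- rep(seq_len(h), each = w)
  c <- rep(seq_len(w), times = h)
  nbr <- vector("list", 9L)
  k <- 0L
  for (di in -1:1) {
    for (dj in -1:1) {
      k <- k + 1L
      rr <- mirror_index(r + di, h)
      cc <- mirror_index(c + dj, w)
      nbr[[k]] <- (rr - 1L) * w + cc
    }
  }
  val <- list(nbr = nbr, sel2 = which(r %% 2L == 1L & c %% 2L == 1L))
  assign(key, val, envir = .gtsr_idx_cache)
  val
}

# weight layout: (9*Cin) x Cout, rows grouped offset-major (block k holds
# the Cin taps of the k-th kernel offset)
conv3_forward <- function(mat, h, w, W, b, stride = 1L) {
  idx <- conv_idx(h, w)
  X9 <- do.call(cbind, lapply(idx$nbr, function(ix) mat[ix, , drop = FALSE]))
  sel <- NULL
  if (stride == 2L) {
    sel <- idx$sel2
    X9 <- X9[sel, , drop = FALSE]
    oh <- (h + 1L) %/% 2L; ow <- (w + 1L) %/% 2L
  } else {
    oh <- h; ow <- w
  }
  Y <- X9 %*% W
  Y <- Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
  list(out = Y, h = oh, w = ow,
       cache = list(X9 = X9, W = W, sel = sel, h = h, w = w,
                    cin = ncol(mat), n = h * w))
}

# scatter-add rows of `block` into dF at (possibly repeated) positions `rows`
scatter_add <- function(dF, rows, block) {
  rs <- rowsum(block, rows)
  u <- as.integer(rownames(rs))
  dF[u, ] <- dF[u, ] + rs
  dF
}

conv3_backward <- function(cache, dY) {
  dW <- crossprod(cache$X9, dY)
  db <- colSums(dY)
  dX9 <- dY %*% t(cache$W)
  idx <- conv_idx(cache$h, cache$w)
  dF <- matrix(0, cache$n, cache$cin)
  for (k in 1:9) {
    cols <- ((k - 1L) * cache$cin + 1L):(k * cache$cin)
    src <- idx$nbr[[k]]
    if (!is.null(cache$sel)) src <- src[cache$sel]
    dF <- scatter_add(dF, src, dX9[, cols, drop = FALSE])
  }
  list(dF = dF, dW = dW, db = db)
}

lrelu_forward <- function(x, alpha = 0.2) {
  pos <- x > 0
  list(out = x * ifelse(pos, 1, alpha), cache = list(pos = pos, alpha = alpha))
}

lrelu_backward <- function(cache, dY) {
  dY * ifelse(cache$pos, 1, cache$alpha)
}

.gtsr_up_cache <- new.env(parent = emptyenv())

# nearest-neighbor 2x upsampling index: output position -> input position
up2_idx <- function(h, w) {
  key <- paste0(h, "x", w)
  hit <- .gtsr_up_cache[[key]]
  if (!is.null(hit)) return(hit)
  oh <- 2L * h; ow <- 2L * w
  r <- rep(seq_len(oh), each = ow)
  c <- rep(seq_len(ow), times = oh)
  val <- ((r + 1L) %/% 2L - 1L) * w + (c + 1L) %/% 2L
  assign(key, val, envir = .gtsr_up_cache)
  val
}

upsample2_forward <- function(mat, h, w) {
  ix <- up2_idx(h, w)
  list(out = mat[ix, , drop = FALSE], h = 2L * h, w = 2L * w,
       cache = list(ix = ix, n = h * w))
}

upsample2_backward <- function(cache, dY) {
  rs <- rowsum(dY, cache$ix)
  dF <- matrix(0, cache$n, ncol(dY))
  dF[as.integer(rownames(rs)), ] <- rs
  dF
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# multi-head self-attention WITHOUT the residual: MSA(Z) = [H_1..H_M] W_O,
# H_m = softmax(Q_m K_m' / sqrt(d_m)) V_m, Q_m = Z Wq[, head m cols], etc.
# Head m occupies columns ((m-1)*dm+1):(m*dm) of Wq/Wk/Wv.
msa_forward <- function(Z, p) {
  d <- ncol(Z); M <- p$heads; dm <- d %/% M
  if (d %% M != 0L) stop("token dim ", d, " not divisible by heads ", M)
  Q <- Z %*% p$Wq; K <- Z %*% p$Wk; V <- Z %*% p$Wv
  Hcat <- matrix(0, nrow(Z), d)
  A_list <- vector("list", M)
  for (m in seq_len(M)) {
    cols <- ((m - 1L) * dm + 1L):(m * dm)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dm)
    if (anyNA(S)) stop("NaN in attention scores")
    A <- softmax_rows(S)
    A_list[[m]] <- A
    Hcat[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- Hcat %*% p$Wo
  list(out = out,
       cache = list(Z = Z, Q = Q, K = K, V = V, Hcat = Hcat, A = A_list,
                    p = p, dm = dm))
}

msa_backward <- function(cache, dOut) {
  p <- cache$p; M <- p$heads; dm <- cache$dm
  Z <- cache$Z
  dWo <- crossprod(cache$Hcat, dOut)
  dHcat <- dOut %*% t(p$Wo)
  dQ <- matrix(0, nrow(Z), ncol(Z))
  dK <- dQ; dV <- dQ
  for (m in seq_len(M)) {
    cols <- ((m - 1L) * dm + 1L):(m * dm)
    A <- cache$A[[m]]
    dHm <- dHcat[, cols, drop = FALSE]
    Vm <- cache$V[, cols, drop = FALSE]
    dA <- dHm %*% t(Vm)
    dV[, cols] <- crossprod(A, dHm)
    dS <- A * (dA - rowSums(dA * A))  # softmax Jacobian, row-wise
    dS <- dS / sqrt(dm)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  dZ <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv) + 0
  dWq <- crossprod(Z, dQ); dWk <- crossprod(Z, dK); dWv <- crossprod(Z, dV)
  list(dZ = dZ, grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
}

# --- parameter initialization ------------------------------------------------

init_conv <- function(cin, cout, gain = sqrt(2)) {
  W <- matrix(stats::rnorm(9L * cin * cout, sd = gain / sqrt(9 * cin)),
              9L * cin, cout)
  list(W = W, b = numeric(cout))
}

init_attention_layer <- function(d, heads) {
  sd <- 1 / sqrt(d)
  list(Wq = matrix(stats::rnorm(d * d, sd = sd), d, d),
       Wk = matrix(stats::rnorm(d * d, sd = sd), d, d),
       Wv = matrix(stats::rnorm(d * d, sd = sd), d, d),
       Wo = matrix(stats::rnorm(d * d, sd = sd), d, d),
       heads = heads)
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# accumulate gradient lists (same names/shapes), then scale
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

grads_scale <- function(g, s) lapply(g, function(x) x * s)

# count scalar parameters in a flat named list of arrays
param_count <- function(params) sum(vapply(params, length, numeric(1)))
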