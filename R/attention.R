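# Global-token bottleneck attention.
#
# The bottleneck feature (C x Hb x Wb) is projected to N = Hb*Wb local
# tokens by a 3x3 convolution and row-major flattening; K learnable global
# tokens are prepended; T residual multi-head self-attention layers
# Z <- Z + MSA(Z) refine the token matrix (no layer norm, no feed-forward
# sublayer); the local tokens are split back out and mapped to a feature
# map by a second 3x3 convolution. The global tokens are discarded after
# the stack — their only job is to aggregate and broadcast image-wide
# context through attention.

# (C, H, W) feature array <-> N x C matrix with row-major positions
feat_to_mat <- function(f) {
  d <- dim(f)
  t(matrix(aperm(f, c(1L, 3L, 2L)), d[1], d[2] * d[3]))
}

mat_to_feat <- function(mat, ch, h, w) {
  aperm(array(t(mat), dim = c(ch, w, h)), c(1L, 3L, 2L))
}

#' Project a bottleneck feature into local tokens
#'
#' 3x3 convolution (stride 1, mirror padding) from the feature's channel
#' count to the token dimension, followed by row-major flattening: feature
#' position (r, c) becomes token index `(r-1)*W + c`.
#'
#' @param f numeric array `(C, H, W)`.
#' @param W,b convolution weights (`(9*C) x d` offset-major) and bias
#'   (length `d`), e.g. from a model built by [init_generator].
#' @return an `N x d` matrix of local tokens, `N = H*W`.
#' @export
tokenize <- function(f, W, b) {
  d <- dim(f)
  conv3_forward(feat_to_mat(f), d[2], d[3], W, b)$out
}

#' Concatenate global and local tokens
#'
#' Globals first, locals after; the fixed ordering every other token
#' operation assumes.
#'
#' @param globals `K x d` matrix of global tokens (K may be 0).
#' @param locals `N x d` matrix of local tokens.
#' @return `(K+N) x d` token matrix.
#' @export
concat_tokens <- function(globals, locals) {
  if (ncol(globals) != ncol(locals)) {
    stop("token dimension mismatch: ", ncol(globals), " vs ", ncol(locals))
  }
  rbind(globals, locals)
}

#' Split a token matrix back into global and local parts
#'
#' @param z `(K+N) x d` token matrix.
#' @param k number of leading global tokens.
#' @return list with `globals` (`K x d`) and `locals` (`N x d`).
#' @export
split_tokens <- function(z, k) {
  if (k < 0L || k > nrow(z)) stop("invalid global token count ", k)
  list(globals = z[seq_len(k), , drop = FALSE],
       locals = z[setdiff(seq_len(nrow(z)), seq_len(k)), , drop = FALSE])
}

#' One multi-head self-attention layer (without residual)
#'
#' Computes `MSA(Z) = [H_1, ..., H_M] W_O` with
#' `H_m = softmax(Q_m K_m' / sqrt(d_m)) V_m`, where the per-head queries,
#' keys and values come from right-multiplication by learned projections
#' and `d_m = d / M` is the head dimension. Attention rows are probability
#' vectors. The residual connection `Z + MSA(Z)` is applied by the caller
#' ([global_token_stack]).
#'
#' @param z `(K+N) x d` token matrix.
#' @param params list with `d x d` matrices `Wq`, `Wk`, `Wv`, `Wo` (columns
#'   of the first three grouped per head) and the head count `heads`.
#' @return matrix of the same shape as `z`.
#' @export
msa_layer <- function(z, params) {
  msa_forward(z, params)$out
}

# cached forward through the full stack; params is the generator's flat
# list restricted to the "gt." names, cfg supplies heads/layers/k
gts_forward <- function(mat, h, w, params, heads, layers, k) {
  tok <- conv3_forward(mat, h, w, params[["gt.tok.W"]], params[["gt.tok.b"]])
  G0 <- params[["gt.G0"]]
  Z <- rbind(G0, tok$out)
  msa_caches <- vector("list", layers)
  if (layers > 0L) {
    for (t in seq_len(layers)) {
      p <- list(Wq = params[[paste0("gt.l", t, ".Wq")]],
                Wk = params[[paste0("gt.l", t, ".Wk")]],
                Wv = params[[paste0("gt.l", t, ".Wv")]],
                Wo = params[[paste0("gt.l", t, ".Wo")]],
                heads = heads)
      ms <- msa_forward(Z, p)
      msa_caches[[t]] <- ms$cache
      Z <- Z + ms$out
    }
  }
  n <- h * w
  XT <- Z[k + seq_len(n), , drop = FALSE]
  det <- conv3_forward(XT, h, w, params[["gt.detok.W"]], params[["gt.detok.b"]])
  list(out = det$out,
       cache = list(tok = tok$cache, msa = msa_caches, det = det$cache,
                    k = k, n = n, layers = layers))
}

gts_backward <- function(cache, dOut) {
  grads <- list()
  det <- conv3_backward(cache$det, dOut)
  grads[["gt.detok.W"]] <- det$dW
  grads[["gt.detok.b"]] <- det$db
  d <- ncol(det$dF)
  dZ <- rbind(matrix(0, cache$k, d), det$dF)
  if (cache$layers > 0L) {
    for (t in rev(seq_len(cache$layers))) {
      mb <- msa_backward(cache$msa[[t]], dZ)
      grads[[paste0("gt.l", t, ".Wq")]] <- mb$grads$Wq
      grads[[paste0("gt.l", t, ".Wk")]] <- mb$grads$Wk
      grads[[paste0("gt.l", t, ".Wv")]] <- mb$grads$Wv
      grads[[paste0("gt.l", t, ".Wo")]] <- mb$grads$Wo
      dZ <- dZ + mb$dZ
    }
  }
  grads[["gt.G0"]] <- dZ[seq_len(cache$k), , drop = FALSE]
  dX0 <- dZ[cache$k + seq_len(cache$n), , drop = FALSE]
  tokb <- conv3_backward(cache$tok, dX0)
  grads[["gt.tok.W"]] <- tokb$dW
  grads[["gt.tok.b"]] <- tokb$db
  list(dF = tokb$dF, grads = grads)
}

#' Refine a bottleneck feature with the global-token attention stack
#'
#' Tokenize, prepend the learned global tokens, apply `layers` residual
#' MSA layers (`Z <- Z + MSA(Z)`, literally: no normalization or
#' feed-forward sublayers), drop the global tokens, and map the refined
#' local tokens back to a feature map with a 3x3 convolution. With all
#' output projections `Wo` zeroed the stack reduces exactly to the
#' tokenize/detokenize round trip regardless of depth, since the residual
#' carries the tokens unchanged.
#'
#' @param f numeric array `(C, Hb, Wb)`.
#' @param model a generator model from [init_generator] (its `gt.*`
#'   parameters and attention configuration are used).
#' @return refined feature array of the same shape as `f`.
#' @export
global_token_stack <- function(f, model) {
  d <- dim(f)
  cfg <- model$config
  res <- gts_forward(feat_to_mat(f), d[2], d[3], model$params,
                     heads = cfg$heads, layers = cfg$layers,
                     k = cfg$global_tokens)
  mat_to_feat(res$out, d[1], d[2], d[3])
}
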