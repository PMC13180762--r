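# Time-aware masked hyperedge attention: causally masked multi-head
# self-attention over tokenized hyperedge sequences, post-norm residual
# blocks, and a sigmoid MLP scorer producing per-position prediction scores.

MASK_NEG <- -1e9   # finite stand-in for -Inf, applied before softmax
LN_EPS <- 1e-5

#' Causal attention mask
#'
#' Additive `n x n` mask: 0 at or below the diagonal, a large negative
#' sentinel strictly above it, so no position can attend to future
#' positions.
#'
#' @param n Sequence length.
#' @return `n x n` matrix.
#' @export
causal_mask <- function(n) {
  stopifnot(n >= 1L)
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- MASK_NEG
  M
}

#' Attention block parameters
#'
#' Per-block learnable weights: fused query/key/value projections
#' (`d_token x d_token`, split column-wise into `H` heads of width
#' `d_token / H`), output projection, feed-forward weights, and layer-norm
#' scale/shift for the two post-norm sublayers.
#'
#' @param d_token Token dimension.
#' @param n_heads Number of attention heads `H`; must divide `d_token`.
#' @param ffn_width Feed-forward hidden width (default `2 * d_token`).
#' @param init `"xavier"` or `"zero"` (zero attention/FFN weights; useful
#'   for testing the residual path).
#' @return List of class `attention_params`.
#' @export
attention_params <- function(d_token, n_heads = 2L, ffn_width = 2L * d_token,
                             init = c("xavier", "zero")) {
  init <- match.arg(init)
  if (d_token %% n_heads != 0L)
    stopf("d_token = %d is not divisible by n_heads = %d", d_token, n_heads)
  mk <- function(a, b) {
    if (init == "zero") matrix(0, a, b)
    else matrix(stats::runif(a * b, -sqrt(6 / (a + b)), sqrt(6 / (a + b))), a, b)
  }
  structure(list(
    Wq = mk(d_token, d_token), Wk = mk(d_token, d_token),
    Wv = mk(d_token, d_token), Wo = mk(d_token, d_token),
    F1 = mk(d_token, ffn_width), f1b = numeric(ffn_width),
    F2 = mk(ffn_width, d_token), f2b = numeric(d_token),
    g1 = rep(1, d_token), be1 = numeric(d_token),
    g2 = rep(1, d_token), be2 = numeric(d_token),
    n_heads = as.integer(n_heads)), class = "attention_params")
}

layer_norm <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  n <- nrow(x); k <- ncol(x)
  y <- xhat * matrix(g, n, k, byrow = TRUE) + matrix(b, n, k, byrow = TRUE)
  list(y = y, xhat = xhat, inv = inv)
}

layer_norm_backward <- function(dy, ln, g) {
  dg <- colSums(dy * ln$xhat)
  db <- colSums(dy)
  dxh <- dy * matrix(g, nrow(dy), ncol(dy), byrow = TRUE)
  dx <- ln$inv * (dxh - rowMeans(dxh) - ln$xhat * rowMeans(dxh * ln$xhat))
  list(dx = dx, dg = dg, db = db)
}

#' Masked multi-head self-attention
#'
#' Computes `softmax((Q K' + M) / sqrt(d_token)) V` per head, where `Q`,
#' `K`, `V` are the token projections. Scaling is by `sqrt(d_token)` (the
#' full token dimension, not the per-head width). Each output row is a
#' convex combination of value rows at its own and earlier positions.
#'
#' @param Z `n x d_token` token matrix.
#' @param params [attention_params()].
#' @param M Mask from [causal_mask()].
#' @return List with `heads` (per-head `n x d_head` outputs) and `attn`
#'   (per-head attention weight matrices).
#' @export
masked_attention <- function(Z, params, M = causal_mask(nrow(Z))) {
  d_token <- ncol(Z)
  n <- nrow(Z)
  if (!all(dim(M) == c(n, n))) stopf("mask shape does not match sequence length")
  if (ncol(params$Wq) != d_token) stopf("token dimension mismatch with attention params")
  H <- params$n_heads
  dh <- d_token %/% H
  Q <- Z %*% params$Wq; K <- Z %*% params$Wk; V <- Z %*% params$Wv
  heads <- vector("list", H); attn <- vector("list", H)
  for (h in seq_len(H)) {
    ix <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) + M) / sqrt(d_token)
    A <- row_softmax(S)
    attn[[h]] <- A
    heads[[h]] <- A %*% V[, ix, drop = FALSE]
  }
  list(heads = heads, attn = attn)
}

# Full encoder block forward with cache (multi-head attention, residual,
# layer norm, position-wise FFN with ReLU, residual, layer norm; post-norm).
block_forward <- function(Z, p) {
  d_token <- ncol(Z)
  n <- nrow(Z)
  H <- p$n_heads
  dh <- d_token %/% H
  M <- causal_mask(n)
  Q <- Z %*% p$Wq; K <- Z %*% p$Wk; V <- Z %*% p$Wv
  O <- matrix(0, n, d_token)
  attn <- vector("list", H)
  for (h in seq_len(H)) {
    ix <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) + M) / sqrt(d_token)
    A <- row_softmax(S)
    attn[[h]] <- A
    O[, ix] <- A %*% V[, ix, drop = FALSE]
  }
  MH <- O %*% p$Wo
  R1 <- Z + MH
  ln1 <- layer_norm(R1, p$g1, p$be1)
  FPre <- ln1$y %*% p$F1 + matrix(p$f1b, n, length(p$f1b), byrow = TRUE)
  FAct <- pmax(FPre, 0)
  FF <- FAct %*% p$F2 + matrix(p$f2b, n, length(p$f2b), byrow = TRUE)
  R2 <- ln1$y + FF
  ln2 <- layer_norm(R2, p$g2, p$be2)
  list(out = ln2$y,
       cache = list(Z = Z, Q = Q, K = K, V = V, O = O, attn = attn,
                    ln1 = ln1, FPre = FPre, FAct = FAct, ln2 = ln2,
                    dh = dh, d_token = d_token))
}

block_backward <- function(dout, cache, p) {
  d_token <- cache$d_token
  H <- p$n_heads
  dh <- cache$dh
  l2 <- layer_norm_backward(dout, cache$ln2, p$g2)
  dR2 <- l2$dx
  dFF <- dR2
  dF2 <- crossprod(cache$FAct, dFF)
  df2b <- colSums(dFF)
  dFAct <- tcrossprod(dFF, p$F2)
  dFPre <- dFAct * (cache$FPre > 0)
  dF1 <- crossprod(cache$ln1$y, dFPre)
  df1b <- colSums(dFPre)
  dL1 <- dR2 + tcrossprod(dFPre, p$F1)
  l1 <- layer_norm_backward(dL1, cache$ln1, p$g1)
  dR1 <- l1$dx
  dZ <- dR1
  dMH <- dR1
  dWo <- crossprod(cache$O, dMH)
  dO <- tcrossprod(dMH, p$Wo)
  dQ <- matrix(0, nrow(dout), d_token)
  dK <- matrix(0, nrow(dout), d_token)
  dV <- matrix(0, nrow(dout), d_token)
  for (h in seq_len(H)) {
    ix <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$attn[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, ix, drop = FALSE])
    dV[, ix] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))     # softmax rows; masked entries have A = 0
    dS <- dS / sqrt(d_token)
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE]
    dK[, ix] <- crossprod(dS, cache$Q[, ix, drop = FALSE])
  }
  dZ <- dZ + tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dZ = dZ,
       grads = list(Wq = crossprod(cache$Z, dQ), Wk = crossprod(cache$Z, dK),
                    Wv = crossprod(cache$Z, dV), Wo = dWo,
                    F1 = dF1, f1b = df1b, F2 = dF2, f2b = df2b,
                    g1 = l1$dg, be1 = l1$db, g2 = l2$dg, be2 = l2$db))
}

#' Transformer encoder block
#'
#' One causally masked multi-head attention sublayer and one position-wise
#' feed-forward sublayer, each followed by a residual connection and layer
#' normalization (post-norm). Causality is preserved end to end: output row
#' `k` depends only on tokens at positions `<= k`.
#'
#' @param Z `n x d_token` token matrix.
#' @param params [attention_params()].
#' @return `n x d_token` matrix of contextualized embeddings.
#' @export
encoder_block <- function(Z, params) block_forward(Z, params)$out

#' Scorer parameters
#'
#' Two-layer position-wise MLP with ReLU hidden activation and a final
#' sigmoid. The final layer initializes to zero so an untrained scorer
#' outputs 0.5 everywhere.
#'
#' @param d_token Input dimension.
#' @param hidden Hidden width (default `d_token`).
#' @return List of class `scorer_params` with `S1`, `s1b`, `S2`, `s2b`.
#' @export
scorer_params <- function(d_token, hidden = d_token) {
  structure(list(
    S1 = matrix(stats::runif(d_token * hidden, -sqrt(6 / (d_token + hidden)),
                             sqrt(6 / (d_token + hidden))), d_token, hidden),
    s1b = numeric(hidden), S2 = matrix(0, hidden, 1L), s2b = 0),
    class = "scorer_params")
}

scorer_forward <- function(Hseq, p) {
  U1 <- Hseq %*% p$S1 + matrix(p$s1b, nrow(Hseq), length(p$s1b), byrow = TRUE)
  UA <- pmax(U1, 0)
  logit <- drop(UA %*% p$S2) + p$s2b
  list(s = sigmoid(logit), logit = logit,
       cache = list(Hseq = Hseq, U1 = U1, UA = UA))
}

scorer_backward <- function(dlogit, cache, p) {
  dlogit <- matrix(dlogit, ncol = 1L)
  dS2 <- crossprod(cache$UA, dlogit)
  ds2b <- sum(dlogit)
  dUA <- tcrossprod(dlogit, p$S2)
  dU1 <- dUA * (cache$U1 > 0)
  list(dH = tcrossprod(dU1, p$S1),
       grads = list(S1 = crossprod(cache$Hseq, dU1), s1b = colSums(dU1),
                    S2 = dS2, s2b = ds2b))
}

#' Per-position prediction scores
#'
#' Applies the sigmoid MLP scorer independently at each sequence position;
#' scores lie strictly in (0, 1).
#'
#' @param Hseq `n x d_token` contextualized embeddings.
#' @param params [scorer_params()].
#' @return Numeric vector of `n` scores.
#' @export
score_sequence <- function(Hseq, params) scorer_forward(Hseq, params)$s
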