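## Low-level differentiable layer primitives.
##
## All layers operate on a single image: feature maps are (H, W, C) arrays,
## token matrices are (T, D).  Each *_fwd returns list(out, cache); each
## *_bwd takes the upstream gradient plus the cache and returns the input
## gradient and parameter gradients.  Convolutions are 3x3, zero-padded,
## realised as im2col matrix products; weights are stored as
## (9*Cin x Cout) matrices so the whole network is plain BLAS.

conv2d_fwd <- function(x, W, b, stride) {
  d <- dim(x)
  col <- cpp_im2col(x, d[1], d[2], d[3], stride)
  out <- col %*% W + rep(b, each = nrow(col))
  Ho <- (d[1] - 1L) %/% stride + 1L
  Wo <- (d[2] - 1L) %/% stride + 1L
  list(out = array(out, c(Ho, Wo, length(b))),
       cache = list(col = col, H = d[1], W = d[2], C = d[3],
                    stride = stride, Ho = Ho, Wo = Wo))
}

conv2d_bwd <- function(dout, W, cache) {
  dmat <- matrix(dout, cache$Ho * cache$Wo, ncol(W))
  dW <- crossprod(cache$col, dmat)
  db <- colSums(dmat)
  dcol <- tcrossprod(dmat, W)
  dx <- cpp_col2im(dcol, cache$H, cache$W, cache$C, cache$stride)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache

## 1x1 convolution == per-pixel linear map over channels.
conv1x1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  out <- xm %*% W + rep(b, each = nrow(xm))
  list(out = array(out, c(d[1], d[2], ncol(W))), cache = list(xm = xm, d = d))
}

conv1x1_bwd <- function(dout, W, cache) {
  dmat <- matrix(dout, nrow(cache$xm), ncol(W))
  list(dx = array(tcrossprod(dmat, W), cache$d),
       dW = crossprod(cache$xm, dmat), db = colSums(dmat))
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(dout) {
  d <- dim(dout)
  o <- seq.int(1L, d[1], 2L); e <- o + 1L
  oc <- seq.int(1L, d[2], 2L); ec <- oc + 1L
  dout[o, oc, , drop = FALSE] + dout[e, oc, , drop = FALSE] +
    dout[o, ec, , drop = FALSE] + dout[e, ec, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

linear_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = X)
}

linear_bwd <- function(dout, W, cache) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache, dout),
       db = colSums(dout))
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  out <- xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- dout * rep(cache$g, each = nrow(dout))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

gelu_fwd <- function(x) list(out = x * stats::pnorm(x), cache = x)
gelu_bwd <- function(dout, cache)
  dout * (stats::pnorm(cache) + cache * stats::dnorm(cache))

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

## Multi-head self-attention, pre-projected by Wq/Wk/Wv, output mixed by Wo.
attention_fwd <- function(X, p, nh) {
  D <- ncol(X); dh <- D %/% nh
  Q <- X %*% p$q.W + rep(p$q.b, each = nrow(X))
  K <- X %*% p$k.W + rep(p$k.b, each = nrow(X))
  V <- X %*% p$v.W + rep(p$v.b, each = nrow(X))
  O <- matrix(0, nrow(X), D)
  A <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    A[[h]] <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE],
                                      K[, cols, drop = FALSE]) / sqrt(dh))
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  out <- O %*% p$o.W + rep(p$o.b, each = nrow(X))
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, A = A, O = O,
                               nh = nh, dh = dh))
}

attention_bwd <- function(dout, p, cache) {
  X <- cache$X; nh <- cache$nh; dh <- cache$dh
  g <- list(o.W = crossprod(cache$O, dout), o.b = colSums(dout))
  dO <- tcrossprod(dout, p$o.W)
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- dQ; dV <- dQ
  for (h in seq_len(nh)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  g$q.W <- crossprod(X, dQ); g$q.b <- colSums(dQ)
  g$k.W <- crossprod(X, dK); g$k.b <- colSums(dK)
  g$v.W <- crossprod(X, dV); g$v.b <- colSums(dV)
  g$dx <- tcrossprod(dQ, p$q.W) + tcrossprod(dK, p$k.W) +
    tcrossprod(dV, p$v.W)
  g
}
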