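# Elementary differentiable layers used by the encoder-decoder model.
# Each .xxxForward returns a cache for the matching .xxxBackward; all
# gradients are exact reverse-mode derivatives, verified against finite
# differences in the test suite.

# sigmoid-approximated GELU (the common fast variant)
.gelu <- function(x) x / (1 + exp(-1.702 * x))
.dgelu <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

.softmaxRows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

.layernormForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

.layernormBackward <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# multi-head scaled dot-product attention (no projection biases)
.attnForward <- function(Xq, Xkv, Wq, Wk, Wv, Wo, nHeads, causal = FALSE) {
  D <- ncol(Xq); dh <- D %/% nHeads
  Q <- Xq %*% Wq; K <- Xkv %*% Wk; V <- Xkv %*% Wv
  Tq <- nrow(Xq); Tk <- nrow(Xkv)
  O <- matrix(0, Tq, D)
  A <- array(0, dim = c(Tq, Tk, nHeads))
  for (h in seq_len(nHeads)) {
    ix <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(dh)
    if (causal && Tq > 1L) S[upper.tri(S)] <- -Inf
    Ah <- .softmaxRows(S)
    A[, , h] <- Ah
    O[, ix] <- Ah %*% V[, ix, drop = FALSE]
  }
  list(out = O %*% Wo, Q = Q, K = K, V = V, A = A, O = O,
       Xq = Xq, Xkv = Xkv, causal = causal)
}

.attnBackward <- function(dOut, cache, Wq, Wk, Wv, Wo, nHeads) {
  D <- ncol(cache$Q); dh <- D %/% nHeads
  dWo <- t(cache$O) %*% dOut
  dO <- dOut %*% t(Wo)
  dQ <- matrix(0, nrow(cache$Q), D)
  dK <- matrix(0, nrow(cache$K), D)
  dV <- matrix(0, nrow(cache$V), D)
  for (h in seq_len(nHeads)) {
    ix <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- cache$A[, , h]
    if (is.null(dim(Ah))) Ah <- matrix(Ah, nrow(cache$Q), nrow(cache$K))
    dOh <- dO[, ix, drop = FALSE]
    dA <- dOh %*% t(cache$V[, ix, drop = FALSE])
    dV[, ix] <- t(Ah) %*% dOh
    dS <- Ah * (dA - rowSums(dA * Ah))
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE] / sqrt(dh)
    dK[, ix] <- t(dS) %*% cache$Q[, ix, drop = FALSE] / sqrt(dh)
  }
  list(dXq = dQ %*% t(Wq), dXkv = dK %*% t(Wk) + dV %*% t(Wv),
       dWq = t(cache$Xq) %*% dQ, dWk = t(cache$Xkv) %*% dK,
       dWv = t(cache$Xkv) %*% dV, dWo = dWo)
}

.ffnForward <- function(X, W1, b1, W2, b2) {
  Z <- X %*% W1 + rep(b1, each = nrow(X))
  Ahat <- .gelu(Z)
  list(out = Ahat %*% W2 + rep(b2, each = nrow(X)), Z = Z, Ahat = Ahat, X = X)
}

.ffnBackward <- function(dY, cache, W1, W2) {
  dAhat <- dY %*% t(W2)
  dZ <- dAhat * .dgelu(cache$Z)
  list(dX = dZ %*% t(W1),
       dW1 = t(cache$X) %*% dZ, db1 = colSums(dZ),
       dW2 = t(cache$Ahat) %*% dY, db2 = colSums(dY))
}

# row shift with zero padding: positive k moves rows toward the start
.rowShift <- function(X, k) {
  L <- nrow(X)
  out <- matrix(0, L, ncol(X))
  if (k >= 0) {
    if (k < L) out[seq_len(L - k), ] <- X[(k + 1L):L, , drop = FALSE]
  } else {
    if (-k < L) out[(1L - k):L, ] <- X[seq_len(L + k), , drop = FALSE]
  }
  out
}

# dilated 1-D convolution, 'same' zero padding; K is (width, Din, Dout)
.convForward <- function(X, K, b, dilation = 1L) {
  w <- dim(K)[1L]
  c0 <- (w + 1L) %/% 2L
  Y <- matrix(rep(b, each = nrow(X)), nrow(X), dim(K)[3L])
  for (t in seq_len(w)) {
    off <- (t - c0) * dilation
    Y <- Y + .rowShift(X, off) %*% K[t, , ]
  }
  list(out = Y, X = X)
}

.convBackward <- function(dY, cache, K, dilation = 1L) {
  w <- dim(K)[1L]
  c0 <- (w + 1L) %/% 2L
  dX <- matrix(0, nrow(dY), dim(K)[2L])
  dK <- array(0, dim = dim(K))
  for (t in seq_len(w)) {
    off <- (t - c0) * dilation
    dK[t, , ] <- t(.rowShift(cache$X, off)) %*% dY
    dX <- dX + .rowShift(dY, -off) %*% t(K[t, , ])
  }
  list(dX = dX, dK = dK, db = colSums(dY))
}

.sinusoidalPE <- function(Tn, D) {
  pos <- seq_len(Tn) - 1L
  pe <- matrix(0, Tn, D)
  for (k in seq_len(ceiling(D / 2))) {
    freq <- 1 / (10000^((2 * (k - 1)) / D))
    pe[, 2L * k - 1L] <- sin(pos * freq)
    if (2L * k <= D) pe[, 2L * k] <- cos(pos * freq)
  }
  pe
}
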