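#' LFNet layer configuration
#'
#' The Local Filter Network analyses hidden representations with a
#' short-time Fourier transform (Hann window, hop of half the window
#' length), multiplies each frame elementwise by a learned complex filter,
#' sparsifies with a soft-shrink nonlinearity, inverts the transform by
#' normalized overlap-add and adds a residual.
#'
#' The default window of 54 positions is even and divisible by 6, so the
#' 3-nt codon period maps to an exact frequency bin (bin 18) and the hop
#' is integral.
#'
#' @param windowLength STFT window length in positions (even).
#' @param hiddenDim hidden dimension D of the representations.
#' @param softshrinkThreshold nonnegative soft-shrink sparsity threshold,
#'   applied independently to real and imaginary parts.
#' @param nLayers number of stacked LFNet layers (used by the encoder).
#' @return a validated config list.
#' @export
lfnetConfig <- function(windowLength = 54L, hiddenDim = 32L,
                        softshrinkThreshold = 0, nLayers = 1L) {
  stopifnot(windowLength %% 2L == 0L, windowLength >= 4L,
            softshrinkThreshold >= 0, hiddenDim >= 1L)
  list(windowLength = as.integer(windowLength),
       hop = as.integer(windowLength / 2L),
       nBins = as.integer(windowLength / 2L + 1L),
       hiddenDim = as.integer(hiddenDim),
       softshrinkThreshold = softshrinkThreshold,
       nLayers = as.integer(nLayers))
}

# Hann window, half-sample shifted so w[n] + w[n + hop] == 1 exactly.
# With centered framing (a leading pad of one hop plus zero-padding to
# complete the final frame) every signal position is covered by exactly
# two frames whose window weights sum to 1, so plain overlap-add gives
# perfect reconstruction at hop = window/2 for any signal length, with a
# well-conditioned (unit) synthesis envelope even at the boundaries.
.hann <- function(W) 0.5 * (1 - cos(2 * pi * (seq_len(W) - 0.5) / W))

.nFrames <- function(L, W, hop) as.integer(ceiling(L / hop)) + 1L

#' Short-time Fourier transform of a hidden representation
#'
#' Hann-windowed, half-overlapping real-to-complex transforms along the
#' length axis, independently per hidden dimension.  Framing is centered:
#' the signal is padded with one hop of zeros in front and zeros to
#' complete the final frame, so ceiling(L / hop) + 1 frames cover every
#' position with unit total window weight.
#'
#' @param H numeric L x D matrix.
#' @param config an \code{\link{lfnetConfig}}.
#' @return complex array of dimension (frames, bins, D) with
#'   bins = windowLength/2 + 1.
#' @export
stftMatrix <- function(H, config) {
  L <- nrow(H); D <- ncol(H)
  W <- config$windowLength; hop <- config$hop; B <- config$nBins
  nF <- .nFrames(L, W, hop)
  Lp <- (nF - 1L) * hop + W
  Hp <- rbind(matrix(0, hop, D), H, matrix(0, Lp - L - hop, D))
  w <- .hann(W)
  # batch all frames into one W x (nF * D) matrix for a single FFT call
  idx <- outer(seq_len(W), (seq_len(nF) - 1L) * hop, `+`)     # W x nF
  segs <- matrix(0, W, nF * D)
  for (d in seq_len(D))
    segs[, (d - 1L) * nF + seq_len(nF)] <- Hp[idx, d] * w
  ft <- stats::mvfft(segs)[seq_len(B), , drop = FALSE]
  aperm(array(ft, dim = c(B, nF, D)), c(2L, 1L, 3L))
}

.softshrink <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

#' Apply a learned complex filter to STFT frames
#'
#' Elementwise complex multiplication of every frame by the filter matrix,
#' followed by soft-shrink on real and imaginary parts.
#'
#' @param frames complex (frames, bins, D) array from
#'   \code{\link{stftMatrix}}.
#' @param W complex bins x D filter matrix.
#' @param threshold nonnegative soft-shrink threshold.
#' @return filtered frames, same shape.
#' @export
applyFilter <- function(frames, W, threshold = 0) {
  d <- dim(frames)
  if (d[2L] != nrow(W) || d[3L] != ncol(W))
    stop("filter shape (", nrow(W), "x", ncol(W),
         ") does not match frames (", d[2L], "x", d[3L], ")")
  v <- frames * rep(W, each = d[1L])
  if (threshold > 0)
    v <- complex(real = .softshrink(Re(v), threshold),
                 imaginary = .softshrink(Im(v), threshold))
  array(v, dim = d)
}

#' Inverse short-time Fourier transform
#'
#' Hermitian-extends each frame, inverts the FFT and overlap-adds; with
#' the centered Hann framing of \code{\link{stftMatrix}} the window
#' weights covering each position sum to exactly 1, giving perfect
#' reconstruction at hop = window/2 for any length.  Output is cropped to
#' \code{originalLength}.
#'
#' @param frames complex (frames, bins, D) array.
#' @param config an \code{\link{lfnetConfig}}.
#' @param originalLength length L to crop the output to.
#' @return numeric L x D matrix.
#' @export
istftMatrix <- function(frames, config, originalLength) {
  d <- dim(frames)
  nF <- d[1L]; B <- d[2L]; D <- d[3L]
  W <- config$windowLength; hop <- config$hop
  Lp <- (nF - 1L) * hop + W
  Fb <- matrix(aperm(frames, c(2L, 1L, 3L)), B, nF * D)   # bins x (frame*dim)
  full <- matrix(0i, W, nF * D)
  full[seq_len(B), ] <- Fb
  if (B > 2L)
    full[W - (2:(B - 1L)) + 2L, ] <- Conj(Fb[2:(B - 1L), , drop = FALSE])
  tm <- array(Re(stats::mvfft(full, inverse = TRUE)) / W, dim = c(W, nF, D))
  ola <- matrix(0, Lp, D)
  for (f in seq_len(nF)) {
    s <- (f - 1L) * hop
    ola[(s + 1L):(s + W), ] <- ola[(s + 1L):(s + W), ] + tm[, f, ]
  }
  ola[hop + seq_len(originalLength), , drop = FALSE]
}

#' One LFNet layer forward pass
#'
#' \code{istft(softshrink(stft(x) * W)) + x}: frequency-domain filtering
#' of the representation plus a residual carrying the previous one.
#'
#' @param H numeric L x D input matrix.
#' @param W complex bins x D filter.
#' @param config an \code{\link{lfnetConfig}}.
#' @return numeric L x D output matrix.
#' @export
lfnetForward <- function(H, W, config) {
  frames <- stftMatrix(H, config)
  filt <- applyFilter(frames, W, config$softshrinkThreshold)
  istftMatrix(filt, config, nrow(H)) + H
}

# --- internal forward with cache, and adjoints, for backpropagation ----

.lfnetForwardCache <- function(H, W, config) {
  frames <- stftMatrix(H, config)
  d <- dim(frames)
  Wrep <- array(rep(W, each = d[1L]), dim = d)
  pre <- frames * Wrep
  thr <- config$softshrinkThreshold
  filt <- if (thr > 0)
    array(complex(real = .softshrink(Re(pre), thr),
                  imaginary = .softshrink(Im(pre), thr)), dim = d)
  else pre
  out <- istftMatrix(filt, config, nrow(H)) + H
  list(out = out, frames = frames, pre = pre, Wrep = Wrep, L = nrow(H))
}

# adjoint of istftMatrix: dOut (L x D) -> complex frame gradients
.istftAdjoint <- function(dOut, config, nF) {
  L <- nrow(dOut); D <- ncol(dOut)
  W <- config$windowLength; hop <- config$hop; B <- config$nBins
  Lp <- (nF - 1L) * hop + W
  g <- matrix(0, Lp, D)
  g[hop + seq_len(L), ] <- dOut
  cfac <- c(1, rep(2, max(0L, B - 2L)), 1)[seq_len(B)]
  idx <- outer(seq_len(W), (seq_len(nF) - 1L) * hop, `+`)
  segs <- matrix(0, W, nF * D)
  for (d in seq_len(D))
    segs[, (d - 1L) * nF + seq_len(nF)] <- g[idx, d]
  G <- stats::mvfft(segs)[seq_len(B), , drop = FALSE] * (cfac / W)
  aperm(array(G, dim = c(B, nF, D)), c(2L, 1L, 3L))
}

# adjoint of stftMatrix: complex frame gradients -> dH (L x D)
.stftAdjoint <- function(dFrames, config, L) {
  d <- dim(dFrames)
  nF <- d[1L]; B <- d[2L]; D <- d[3L]
  W <- config$windowLength; hop <- config$hop
  Lp <- (nF - 1L) * hop + W
  w <- .hann(W)
  Gpad <- matrix(0i, W, nF * D)
  Gpad[seq_len(B), ] <- matrix(aperm(dFrames, c(2L, 1L, 3L)), B, nF * D)
  tm <- array(Re(stats::mvfft(Gpad, inverse = TRUE)) * w, dim = c(W, nF, D))
  dH <- matrix(0, Lp, D)
  for (f in seq_len(nF)) {
    s <- (f - 1L) * hop
    dH[(s + 1L):(s + W), ] <- dH[(s + 1L):(s + W), ] + tm[, f, ]
  }
  dH[hop + seq_len(L), , drop = FALSE]
}

# backward through one LFNet layer; returns dH and dW (complex)
.lfnetBackward <- function(dOut, cache, W, config) {
  thr <- config$softshrinkThreshold
  dFilt <- .istftAdjoint(dOut, config, dim(cache$frames)[1L])
  if (thr > 0) {
    pre <- cache$pre
    dFilt <- complex(real = Re(dFilt) * (abs(Re(pre)) > thr),
                     imaginary = Im(dFilt) * (abs(Im(pre)) > thr))
    dFilt <- array(dFilt, dim = dim(cache$frames))
  }
  dFrames <- array(dFilt * Conj(cache$Wrep), dim = dim(cache$frames))
  dWfull <- array(dFilt * Conj(cache$frames), dim = dim(cache$frames))
  dW <- colSums(dWfull, dims = 1L)
  dH <- .stftAdjoint(dFrames, config, cache$L) + dOut
  list(dH = dH, dW = dW)
}

#' Export filter spectra in polar form
#'
#' Magnitude and phase of every complex filter entry, with each frequency
#' bin annotated by its equivalent nucleotide period
#' (windowLength / bin index; the DC bin has infinite period).
#'
#' @param filters list of complex bins x D filter matrices (one per
#'   layer), or a single matrix.
#' @param windowLength STFT window length the filters belong to.
#' @return data.frame with columns \code{layer}, \code{bin}, \code{dim},
#'   \code{magnitude}, \code{phase}, \code{period}.
#' @export
filterSpectra <- function(filters, windowLength) {
  if (is.matrix(filters)) filters <- list(filters)
  out <- lapply(seq_along(filters), function(l) {
    W <- filters[[l]]
    B <- nrow(W); D <- ncol(W)
    bin <- rep(seq_len(B) - 1L, D)
    data.frame(layer = l, bin = bin, dim = rep(seq_len(D), each = B),
               magnitude = as.vector(Mod(W)), phase = as.vector(Arg(W)),
               period = ifelse(bin == 0L, Inf, windowLength / bin))
  })
  do.call(rbind, out)
}
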