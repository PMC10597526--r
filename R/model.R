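# Vocabulary ------------------------------------------------------------

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Output vocabulary of the sequence model
#'
#' Twenty amino acids, the class tokens \code{<PC>} and \code{<NC>}
#' (legal only at the first output position), start-of-sequence and
#' end-of-sequence.  Inputs use the nucleotide alphabet A, C, G, U.
#'
#' @return character vector of output tokens in id order.
#' @export
outputVocab <- function() c(AA_LETTERS, "<PC>", "<NC>", "<s>", "</s>")

.TOK <- local({
  v <- c(AA_LETTERS, "<PC>", "<NC>", "<s>", "</s>")
  stats::setNames(seq_along(v), v)
})

#' One-hot encode an RNA sequence
#'
#' @param sequence character RNA sequence over A,C,G,U.
#' @return numeric L x 4 matrix with columns A, C, G, U.
#' @export
seqToOneHot <- function(sequence) {
  ch <- strsplit(sequence, "")[[1L]]
  idx <- match(ch, RNA_BASES)
  if (anyNA(idx)) stop("unknown token in input sequence: ",
                       paste(unique(ch[is.na(idx)]), collapse = ","))
  X <- matrix(0, length(ch), 4L, dimnames = list(NULL, RNA_BASES))
  X[cbind(seq_along(ch), idx)] <- 1
  X
}

# Configuration ----------------------------------------------------------

#' Model architecture configuration
#'
#' @param encoder \code{"lfnet"} or \code{"cnn"}.
#' @param nEncoderLayers,nDecoderLayers stack depths.
#' @param hiddenDim embedding dimension D.
#' @param nHeads decoder attention heads (must divide D).
#' @param ffDim feed-forward inner dimension.
#' @param window LFNet STFT window length.
#' @param softshrink LFNet soft-shrink threshold.
#' @param cnnKernel CNN kernel width (odd).
#' @param dilationDoubling double CNN dilation with each layer.
#' @param task training task the model is intended for
#'   (\code{"seq"}, \code{"seq_wt"}, \code{"class"}, \code{"start"}).
#' @return config list.
#' @export
modelConfig <- function(encoder = c("lfnet", "cnn"), nEncoderLayers = 2L,
                        nDecoderLayers = 1L, hiddenDim = 32L, nHeads = 4L,
                        ffDim = 2L * hiddenDim, window = 54L,
                        softshrink = 0.0, cnnKernel = 3L,
                        dilationDoubling = TRUE,
                        task = c("class", "seq", "seq_wt", "start")) {
  encoder <- match.arg(encoder)
  task <- match.arg(task)
  stopifnot(hiddenDim %% nHeads == 0L, cnnKernel %% 2L == 1L,
            nEncoderLayers >= 1L, nDecoderLayers >= 1L)
  list(encoder = encoder, nEncoderLayers = as.integer(nEncoderLayers),
       nDecoderLayers = as.integer(nDecoderLayers),
       hiddenDim = as.integer(hiddenDim), nHeads = as.integer(nHeads),
       ffDim = as.integer(ffDim), window = as.integer(window),
       softshrink = softshrink, cnnKernel = as.integer(cnnKernel),
       dilationDoubling = dilationDoubling, task = task)
}

.lfcfg <- function(cfg) lfnetConfig(cfg$window, cfg$hiddenDim, cfg$softshrink)

# Parameter initialization ----------------------------------------------

.glorot <- function(fi, fo) matrix(stats::rnorm(fi * fo, sd = sqrt(2 / (fi + fo))), fi, fo)

#' Build a model with randomly initialized parameters
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed integer seed for initialization.
#' @return a \code{\link{SeqModel}}.
#' @export
buildModel <- function(config, seed = 1L) {
  set.seed(seed)
  D <- config$hiddenDim; Dff <- config$ffDim
  V <- length(.TOK)
  p <- list(Ein = .glorot(4L, D))
  for (l in seq_len(config$nEncoderLayers)) {
    pre <- paste0("enc", l, ".")
    if (config$encoder == "lfnet") {
      B <- config$window / 2L + 1L
      p[[paste0(pre, "Wf")]] <- array(stats::rnorm(B * D * 2, sd = 0.1),
                                      dim = c(B, D, 2L))
      p[[paste0(pre, "lng")]] <- rep(1, D)
      p[[paste0(pre, "lnb")]] <- rep(0, D)
      p[[paste0(pre, "W1")]] <- .glorot(D, Dff)
      p[[paste0(pre, "b1")]] <- rep(0, Dff)
      p[[paste0(pre, "W2")]] <- .glorot(Dff, D)
      p[[paste0(pre, "b2")]] <- rep(0, D)
    } else {
      w <- config$cnnKernel
      p[[paste0(pre, "K")]] <- array(stats::rnorm(w * D * D, sd = sqrt(2 / (w * D + D))),
                                     dim = c(w, D, D))
      p[[paste0(pre, "cb")]] <- rep(0, D)
      p[[paste0(pre, "lng")]] <- rep(1, D)
      p[[paste0(pre, "lnb")]] <- rep(0, D)
    }
  }
  p$Eout <- .glorot(V, D)
  for (l in seq_len(config$nDecoderLayers)) {
    pre <- paste0("dec", l, ".")
    for (nm in c("sWq", "sWk", "sWv", "sWo", "cWq", "cWk", "cWv", "cWo"))
      p[[paste0(pre, nm)]] <- .glorot(D, D)
    for (nm in c("ln1", "ln2", "ln3")) {
      p[[paste0(pre, nm, "g")]] <- rep(1, D)
      p[[paste0(pre, nm, "b")]] <- rep(0, D)
    }
    p[[paste0(pre, "F1")]] <- .glorot(D, Dff)
    p[[paste0(pre, "f1b")]] <- rep(0, Dff)
    p[[paste0(pre, "F2")]] <- .glorot(Dff, D)
    p[[paste0(pre, "f2b")]] <- rep(0, D)
  }
  p$Wout <- .glorot(D, V)
  p$bout <- rep(0, V)
  p$Pw <- matrix(stats::rnorm(D, sd = sqrt(1 / D)), D, 1L)
  p$Pb <- 0
  new("SeqModel", config = config, params = p)
}

.filterComplex <- function(Wf) {
  matrix(complex(real = Wf[, , 1L], imaginary = Wf[, , 2L]),
         dim(Wf)[1L], dim(Wf)[2L])
}

# Encoder ----------------------------------------------------------------

.encodeForward <- function(p, cfg, X) {
  H <- X %*% p$Ein
  caches <- vector("list", cfg$nEncoderLayers)
  lf <- if (cfg$encoder == "lfnet") .lfcfg(cfg)
  for (l in seq_len(cfg$nEncoderLayers)) {
    pre <- paste0("enc", l, ".")
    if (cfg$encoder == "lfnet") {
      Wc <- .filterComplex(p[[paste0(pre, "Wf")]])
      c1 <- .lfnetForwardCache(H, Wc, lf)
      ln <- .layernormForward(c1$out, p[[paste0(pre, "lng")]], p[[paste0(pre, "lnb")]])
      ff <- .ffnForward(ln$out, p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]],
                        p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
      caches[[l]] <- list(lf = c1, ln = ln, ff = ff, Wc = Wc)
      H <- c1$out + ff$out
    } else {
      dil <- if (cfg$dilationDoubling) 2L^(l - 1L) else 1L
      ln <- .layernormForward(H, p[[paste0(pre, "lng")]], p[[paste0(pre, "lnb")]])
      Z <- .gelu(ln$out)
      cv <- .convForward(Z, p[[paste0(pre, "K")]], p[[paste0(pre, "cb")]], dil)
      caches[[l]] <- list(ln = ln, Z = ln$out, cv = cv, dil = dil)
      H <- H + cv$out
    }
  }
  list(H = H, caches = caches, X = X)
}

.encodeBackward <- function(p, cfg, dH, fw) {
  g <- list()
  lf <- if (cfg$encoder == "lfnet") .lfcfg(cfg)
  for (l in rev(seq_len(cfg$nEncoderLayers))) {
    pre <- paste0("enc", l, ".")
    cc <- fw$caches[[l]]
    if (cfg$encoder == "lfnet") {
      fb <- .ffnBackward(dH, cc$ff, p[[paste0(pre, "W1")]], p[[paste0(pre, "W2")]])
      g[[paste0(pre, "W1")]] <- fb$dW1; g[[paste0(pre, "b1")]] <- fb$db1
      g[[paste0(pre, "W2")]] <- fb$dW2; g[[paste0(pre, "b2")]] <- fb$db2
      lb <- .layernormBackward(fb$dX, cc$ln, p[[paste0(pre, "lng")]])
      g[[paste0(pre, "lng")]] <- lb$dg; g[[paste0(pre, "lnb")]] <- lb$db
      dx1 <- dH + lb$dX
      bk <- .lfnetBackward(dx1, cc$lf, cc$Wc, lf)
      g[[paste0(pre, "Wf")]] <- array(c(Re(bk$dW), Im(bk$dW)),
                                      dim = c(nrow(bk$dW), ncol(bk$dW), 2L))
      dH <- bk$dH
    } else {
      cb <- .convBackward(dH, cc$cv, p[[paste0(pre, "K")]], cc$dil)
      g[[paste0(pre, "K")]] <- cb$dK; g[[paste0(pre, "cb")]] <- cb$db
      dZ <- cb$dX * .dgelu(cc$Z)
      lb <- .layernormBackward(dZ, cc$ln, p[[paste0(pre, "lng")]])
      g[[paste0(pre, "lng")]] <- lb$dg; g[[paste0(pre, "lnb")]] <- lb$db
      dH <- dH + lb$dX
    }
  }
  g$Ein <- t(fw$X) %*% dH
  list(grads = g, dX = dH %*% t(p$Ein))
}

# Decoder ----------------------------------------------------------------

.decodeForward <- function(p, cfg, Henc, tokIds) {
  Tn <- length(tokIds)
  Y <- p$Eout[tokIds, , drop = FALSE] + .sinusoidalPE(Tn, cfg$hiddenDim)
  caches <- vector("list", cfg$nDecoderLayers)
  attn <- vector("list", cfg$nDecoderLayers)
  for (l in seq_len(cfg$nDecoderLayers)) {
    pre <- paste0("dec", l, ".")
    sa <- .attnForward(Y, Y, p[[paste0(pre, "sWq")]], p[[paste0(pre, "sWk")]],
                       p[[paste0(pre, "sWv")]], p[[paste0(pre, "sWo")]],
                       cfg$nHeads, causal = TRUE)
    l1 <- .layernormForward(Y + sa$out, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
    ca <- .attnForward(l1$out, Henc, p[[paste0(pre, "cWq")]], p[[paste0(pre, "cWk")]],
                       p[[paste0(pre, "cWv")]], p[[paste0(pre, "cWo")]], cfg$nHeads)
    l2 <- .layernormForward(l1$out + ca$out, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
    ff <- .ffnForward(l2$out, p[[paste0(pre, "F1")]], p[[paste0(pre, "f1b")]],
                      p[[paste0(pre, "F2")]], p[[paste0(pre, "f2b")]])
    l3 <- .layernormForward(l2$out + ff$out, p[[paste0(pre, "ln3g")]], p[[paste0(pre, "ln3b")]])
    caches[[l]] <- list(sa = sa, l1 = l1, ca = ca, l2 = l2, ff = ff, l3 = l3)
    attn[[l]] <- ca$A
    Y <- l3$out
  }
  list(logits = Y %*% p$Wout + rep(p$bout, each = Tn),
       attn = attn, caches = caches, Yfinal = Y, tokIds = tokIds)
}

.decodeBackward <- function(p, cfg, dLogits, fw) {
  g <- list()
  g$Wout <- t(fw$Yfinal) %*% dLogits
  g$bout <- colSums(dLogits)
  dY <- dLogits %*% t(p$Wout)
  dHenc <- NULL
  for (l in rev(seq_len(cfg$nDecoderLayers))) {
    pre <- paste0("dec", l, ".")
    cc <- fw$caches[[l]]
    l3b <- .layernormBackward(dY, cc$l3, p[[paste0(pre, "ln3g")]])
    g[[paste0(pre, "ln3g")]] <- l3b$dg; g[[paste0(pre, "ln3b")]] <- l3b$db
    fb <- .ffnBackward(l3b$dX, cc$ff, p[[paste0(pre, "F1")]], p[[paste0(pre, "F2")]])
    g[[paste0(pre, "F1")]] <- fb$dW1; g[[paste0(pre, "f1b")]] <- fb$db1
    g[[paste0(pre, "F2")]] <- fb$dW2; g[[paste0(pre, "f2b")]] <- fb$db2
    d2 <- l3b$dX + fb$dX
    l2b <- .layernormBackward(d2, cc$l2, p[[paste0(pre, "ln2g")]])
    g[[paste0(pre, "ln2g")]] <- l2b$dg; g[[paste0(pre, "ln2b")]] <- l2b$db
    cab <- .attnBackward(l2b$dX, cc$ca, p[[paste0(pre, "cWq")]], p[[paste0(pre, "cWk")]],
                         p[[paste0(pre, "cWv")]], p[[paste0(pre, "cWo")]], cfg$nHeads)
    g[[paste0(pre, "cWq")]] <- cab$dWq; g[[paste0(pre, "cWk")]] <- cab$dWk
    g[[paste0(pre, "cWv")]] <- cab$dWv; g[[paste0(pre, "cWo")]] <- cab$dWo
    dHenc <- if (is.null(dHenc)) cab$dXkv else dHenc + cab$dXkv
    d1 <- l2b$dX + cab$dXq
    l1b <- .layernormBackward(d1, cc$l1, p[[paste0(pre, "ln1g")]])
    g[[paste0(pre, "ln1g")]] <- l1b$dg; g[[paste0(pre, "ln1b")]] <- l1b$db
    sab <- .attnBackward(l1b$dX, cc$sa, p[[paste0(pre, "sWq")]], p[[paste0(pre, "sWk")]],
                         p[[paste0(pre, "sWv")]], p[[paste0(pre, "sWo")]], cfg$nHeads)
    g[[paste0(pre, "sWq")]] <- sab$dWq; g[[paste0(pre, "sWk")]] <- sab$dWk
    g[[paste0(pre, "sWv")]] <- sab$dWv; g[[paste0(pre, "sWo")]] <- sab$dWo
    dY <- l1b$dX + sab$dXq + sab$dXkv
  }
  dEout <- matrix(0, nrow(p$Eout), ncol(p$Eout))
  for (t in seq_along(fw$tokIds))
    dEout[fw$tokIds[t], ] <- dEout[fw$tokIds[t], ] + dY[t, ]
  g$Eout <- dEout
  list(grads = g, dHenc = dHenc)
}

# Public interfaces ------------------------------------------------------

#' Encode an RNA sequence into per-position hidden states
#'
#' @param model a \code{\link{SeqModel}}.
#' @param sequence character RNA sequence (or an L x 4 one-hot matrix).
#' @return numeric L x D matrix of encoder hidden states.
#' @export
encode <- function(model, sequence) {
  X <- if (is.matrix(sequence)) sequence else seqToOneHot(sequence)
  .encodeForward(model@params, model@config, X)$H
}

#' One decoding step: next-token logits and attention maps
#'
#' Runs the decoder over the given output prefix against precomputed
#' encoder states; returns logits for the next token (at the last prefix
#' position) and the encoder-decoder attention distributions.
#'
#' @param model a \code{\link{SeqModel}}.
#' @param prefixTokens character vector of output-vocabulary tokens,
#'   beginning with \code{"<s>"}.
#' @param encStates L x D matrix from \code{\link{encode}}.
#' @return list with \code{logits} (named vector over the output
#'   vocabulary), \code{allLogits} (T x V matrix), and \code{attention}
#'   (per decoder layer, a T x L x nHeads array of rows summing to 1).
#' @export
decodeStep <- function(model, prefixTokens, encStates) {
  ids <- .TOK[prefixTokens]
  if (anyNA(ids)) stop("unknown output token in prefix")
  if (prefixTokens[1L] != "<s>") stop("prefix must begin with <s>")
  fw <- .decodeForward(model@params, model@config, encStates, ids)
  lg <- fw$logits
  colnames(lg) <- names(.TOK)
  list(logits = lg[nrow(lg), ], allLogits = lg, attention = fw$attn)
}

#' Pointer head: distribution over input positions
#'
#' A single linear layer projects each encoder state to a scalar; a
#' softmax over positions yields the start-codon location distribution.
#'
#' @param model a \code{\link{SeqModel}}.
#' @param encStates L x D matrix from \code{\link{encode}}.
#' @return numeric probability vector of length L summing to 1.
#' @export
pointerForward <- function(model, encStates) {
  s <- as.vector(encStates %*% model@params$Pw) + model@params$Pb
  e <- exp(s - max(s))
  e / sum(e)
}

# scalar coding score S = l_<PC> - l_<NC> at the first decoding position,
# with optional gradient with respect to the dense input X (L x 4)
.scoreForward <- function(model, X, wantGrad = FALSE) {
  p <- model@params; cfg <- model@config
  enc <- .encodeForward(p, cfg, X)
  dec <- .decodeForward(p, cfg, enc$H, .TOK[["<s>"]])
  S <- dec$logits[1L, .TOK[["<PC>"]]] - dec$logits[1L, .TOK[["<NC>"]]]
  if (!wantGrad) return(list(S = S))
  dLogits <- matrix(0, 1L, length(.TOK))
  dLogits[1L, .TOK[["<PC>"]]] <- 1
  dLogits[1L, .TOK[["<NC>"]]] <- -1
  db <- .decodeBackward(p, cfg, dLogits, dec)
  eb <- .encodeBackward(p, cfg, db$dHenc, enc)
  list(S = S, dX = eb$dX)
}

#' Coding score of a sequence
#'
#' \eqn{S = l_{PC} - l_{NC}}: the difference of class-token logits at the
#' first decoding position.  The scale on which all mutation effects
#' (\eqn{\Delta S}) are expressed.
#'
#' @param model a \code{\link{SeqModel}}.
#' @param sequence RNA sequence or L x 4 one-hot/dense matrix.
#' @return numeric scalar.
#' @export
codingScore <- function(model, sequence) {
  X <- if (is.matrix(sequence)) sequence else seqToOneHot(sequence)
  .scoreForward(model, X)$S
}

# Checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, parameters, optimizer state
#' and RNG state, so training can resume exactly.
#'
#' @param checkpoint list as produced during \code{\link{trainModel}}, or
#'   a \code{\link{SeqModel}}.
#' @param path file path.
#' @name checkpoints
#' @export
saveCheckpoint <- function(checkpoint, path) {
  if (is(checkpoint, "SeqModel"))
    checkpoint <- list(config = checkpoint@config, params = checkpoint@params)
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname checkpoints
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  ck$model <- new("SeqModel", config = ck$config, params = ck$params)
  ck
}
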