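# Training objectives ---------------------------------------------------

#' Truncated discrete exponential position weights
#'
#' \eqn{p(i, \lambda) = (1 - e^{-\lambda}) e^{-\lambda i} / (1 -
#' e^{-\lambda N})} for output positions \eqn{i = 0 \ldots N-1}.  Weights
#' sum to 1 and decrease strictly with position for \eqn{\lambda > 0}; as
#' \eqn{\lambda \to 0} they approach the uniform distribution, and for
#' large \eqn{\lambda} all weight concentrates on the first position,
#' interpolating between the full translation objective and the
#' classification-only objective.
#'
#' @param N number of output positions (>= 1).
#' @param lambda decay rate, >= 0 (0 gives the uniform limit).
#' @return numeric weight vector of length N.
#' @export
positionWeights <- function(N, lambda) {
  stopifnot(N >= 1L)
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda == 0) return(rep(1 / N, N))
  i <- seq_len(N) - 1
  w <- (1 - exp(-lambda)) * exp(-lambda * i) / (1 - exp(-lambda * N))
  # guard the extreme-lambda limit where the closed form underflows
  if (!all(is.finite(w)) || sum(w) == 0) w <- c(1, rep(0, N - 1L))
  w / sum(w)
}

#' Objective configuration
#'
#' @param task one of \code{"seq"} (full translation, uniform weights),
#'   \code{"seq_wt"} (position-weighted translation), \code{"class"}
#'   (classification token only), \code{"start"} (start-codon pointer).
#' @param lambda decay rate for \code{seq_wt} (ignored otherwise).
#' @param labelSmoothing optional label smoothing mass in [0, 1).
#' @export
objectiveConfig <- function(task = c("seq", "seq_wt", "class", "start"),
                            lambda = 0.1, labelSmoothing = 0) {
  task <- match.arg(task)
  if (lambda < 0) stop("lambda must be nonnegative")
  stopifnot(labelSmoothing >= 0, labelSmoothing < 1)
  list(task = task, lambda = lambda, labelSmoothing = labelSmoothing)
}

#' Combine per-position losses under an objective
#'
#' \code{seq}: uniform weights (mean); \code{seq_wt}: weighted by
#' \code{\link{positionWeights}}; \code{class}: the first-position loss
#' only.
#'
#' @param perPositionLosses numeric vector of per-position losses.
#' @param objective an \code{\link{objectiveConfig}}.
#' @return scalar loss.
#' @export
sequenceLoss <- function(perPositionLosses, objective) {
  N <- length(perPositionLosses)
  w <- switch(objective$task,
    seq = rep(1 / N, N),
    seq_wt = positionWeights(N, objective$lambda),
    class = c(1, rep(0, N - 1L)),
    stop("sequenceLoss does not apply to task ", objective$task))
  sum(perPositionLosses * w)
}

#' Pointer cross-entropy loss
#'
#' \eqn{-\log p[\mathrm{true}]}, with a floor epsilon guarding
#' degenerate zero-probability targets.
#'
#' @param pointerDistribution probability vector over positions.
#' @param trueIndex 1-based index of the true start position.
#' @param eps probability floor.
#' @export
startLoss <- function(pointerDistribution, trueIndex, eps = 1e-12) {
  -log(max(pointerDistribution[trueIndex], eps))
}

# Batching ---------------------------------------------------------------

#' Length-binned batch plan
#'
#' Examples are sorted by input length and grouped so that no batch's
#' padded token count (batch size times maximum length) exceeds
#' \code{maxTokensPerBatch}.
#'
#' @param maxTokensPerBatch padded token budget per batch.
#' @param gradAccumSteps batches per optimizer step.
#' @export
batchPlan <- function(maxTokensPerBatch = 9000L, gradAccumSteps = 1L) {
  stopifnot(maxTokensPerBatch >= 1L, gradAccumSteps >= 1L)
  list(maxTokens = as.integer(maxTokensPerBatch),
       gradAccumSteps = as.integer(gradAccumSteps))
}

.makeBatches <- function(lens, plan) {
  ord <- order(lens)
  batches <- list()
  cur <- integer(0)
  for (i in ord) {
    cand <- c(cur, i)
    if (length(cand) * max(lens[cand]) > plan$maxTokens && length(cur)) {
      batches[[length(batches) + 1L]] <- cur
      cand <- i
    }
    cur <- cand
  }
  if (length(cur)) batches[[length(batches) + 1L]] <- cur
  batches
}

# Targets ----------------------------------------------------------------

.targetTokens <- function(label, protein, task) {
  if (task == "class")
    return(if (label == "PC") "<PC>" else "<NC>")
  if (label == "PC") c("<PC>", strsplit(protein, "")[[1L]], "</s>")
  else c("<NC>", "</s>")
}

# loss + parameter gradients for one example
.exampleGrad <- function(p, cfg, X, targetIds, w, labelSmoothing = 0) {
  enc <- .encodeForward(p, cfg, X)
  inIds <- c(.TOK[["<s>"]], targetIds[-length(targetIds)])
  dec <- .decodeForward(p, cfg, enc$H, inIds)
  lg <- dec$logits
  m <- lg[cbind(seq_len(nrow(lg)), max.col(lg, ties.method = "first"))]
  lse <- m + log(rowSums(exp(lg - m)))
  logp <- lg - lse
  Tn <- length(targetIds)
  V <- ncol(lg)
  pick <- cbind(seq_len(Tn), targetIds)
  if (labelSmoothing > 0) {
    li <- -(1 - labelSmoothing) * logp[pick] -
      labelSmoothing * rowMeans(logp)
  } else li <- -logp[pick]
  loss <- sum(li * w)
  P <- exp(logp)
  Yt <- matrix(0, Tn, V); Yt[pick] <- 1
  if (labelSmoothing > 0)
    Yt <- (1 - labelSmoothing) * Yt + labelSmoothing / V
  dLogits <- (P - Yt) * w
  db <- .decodeBackward(p, cfg, dLogits, dec)
  eb <- .encodeBackward(p, cfg, db$dHenc, enc)
  grads <- c(db$grads, eb$grads)
  list(loss = loss, grads = grads)
}

.examplePointerGrad <- function(p, cfg, X, trueIndex) {
  enc <- .encodeForward(p, cfg, X)
  s <- as.vector(enc$H %*% p$Pw) + p$Pb
  e <- exp(s - max(s)); pr <- e / sum(e)
  loss <- startLoss(pr, trueIndex)
  dvec <- pr
  dvec[trueIndex] <- dvec[trueIndex] - 1
  dH <- dvec %*% t(p$Pw)
  eb <- .encodeBackward(p, cfg, dH, enc)
  grads <- eb$grads
  grads$Pw <- t(enc$H) %*% matrix(dvec)
  grads$Pb <- sum(dvec)
  list(loss = loss, grads = grads)
}

.addGrads <- function(acc, g, scale = 1) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] * scale
                 else acc[[nm]] + g[[nm]] * scale
  }
  acc
}

.adamStep <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip = 5, weightDecay = 0) {
  gn <- sqrt(sum(vapply(g, function(x) sum(x^2), 0)))
  if (is.finite(gn) && gn > clip) g <- lapply(g, function(x) x * (clip / gn))
  st$t <- st$t + 1L
  corr1 <- 1 - st$beta1pow * beta1; corr2 <- 1 - st$beta2pow * beta2
  st$beta1pow <- st$beta1pow * beta1; st$beta2pow <- st$beta2pow * beta2
  for (nm in names(g)) {
    if (is.null(st$m[[nm]])) { st$m[[nm]] <- g[[nm]] * 0; st$v[[nm]] <- g[[nm]] * 0 }
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- st$m[[nm]] / corr1
    vh <- st$v[[nm]] / corr2
    p[[nm]] <- p[[nm]] - lr * (mh / (sqrt(vh) + eps) + weightDecay * p[[nm]])
  }
  list(p = p, st = st)
}

# Training loop ----------------------------------------------------------

#' Train a model on a TranscriptSet
#'
#' Single-device deterministic training under \code{seed}: Adam with
#' gradient clipping, length-binned batches, optional gradient
#' accumulation, per-epoch validation F1 (first-token classification, or
#' pointer classification for the start task) and best-checkpoint
#' retention.  Aborts with a diagnostic on non-finite loss.
#'
#' @param model a \code{\link{SeqModel}} (or a checkpoint list from a
#'   previous call, to resume).
#' @param transcripts a \code{\link{TranscriptSet}}.
#' @param trainIds,valIds transcript ids for training and validation.
#' @param objective an \code{\link{objectiveConfig}}.
#' @param plan a \code{\link{batchPlan}}.
#' @param epochs training epochs.
#' @param lr peak Adam learning rate.
#' @param lrSchedule \code{"cosine"} (decay to 5\% of peak) or
#'   \code{"constant"}.
#' @param warmupEpochs linear learning-rate ramp over the first epochs
#'   (stabilizes the early phase of the translation tasks).
#' @param weightDecay decoupled weight decay coefficient.
#' @param seed integer seed (ignored when resuming: the checkpoint's RNG
#'   state is restored instead).
#' @param verbose print per-epoch progress.
#' @return checkpoint list with elements \code{model} (best
#'   \code{SeqModel} by validation F1, falling back to final), \code{log}
#'   (data.frame epoch/loss/val_F1), and internal resume state.
#' @export
trainModel <- function(model, transcripts, trainIds, valIds = character(0),
                       objective = objectiveConfig("class"),
                       plan = batchPlan(), epochs = 10L, lr = 2e-3,
                       lrSchedule = c("cosine", "constant"),
                       warmupEpochs = 2L, weightDecay = 1e-4, seed = 1L,
                       verbose = FALSE) {
  lrSchedule <- match.arg(lrSchedule)
  resume <- is.list(model) && !is.null(model$params)
  if (resume) {
    cfg <- model$config; p <- model$params; st <- model$opt
    log <- model$log
    assign(".Random.seed", model$rng, envir = globalenv())
    epoch0 <- max(log$epoch)
  } else {
    cfg <- model@config; p <- model@params
    st <- list(m = list(), v = list(), t = 0L, beta1pow = 1, beta2pow = 1)
    log <- data.frame(epoch = integer(0), loss = numeric(0), val_F1 = numeric(0))
    set.seed(seed)
    epoch0 <- 0L
  }
  task <- objective$task
  idx <- match(trainIds, transcriptIds(transcripts))
  seqs <- transcriptSeqs(transcripts)[idx]
  labs <- transcriptLabels(transcripts)[idx]
  prots <- transcriptProteins(transcripts)[idx]
  cdss <- cdsRanges(transcripts)[idx, , drop = FALSE]
  lens <- nchar(seqs)
  Xs <- lapply(seqs, seqToOneHot)
  batches <- .makeBatches(lens, plan)
  bestF1 <- -Inf; bestP <- p
  for (ep in seq_len(epochs)) {
    lrEp <- if (lrSchedule == "cosine")
      lr * (0.05 + 0.95 * 0.5 * (1 + cos(pi * (ep - 1) / max(1L, epochs - 1L))))
    else lr
    if (warmupEpochs > 0L && (epoch0 + ep) <= warmupEpochs)
      lrEp <- lrEp * (epoch0 + ep) / (warmupEpochs + 1L)
    ord <- sample(length(batches))
    tot <- 0; ntot <- 0L
    accum <- list(); nAcc <- 0L; bAcc <- 0L
    for (bi in ord) {
      b <- batches[[bi]]
      for (i in b) {
        if (task == "start") {
          tix <- if (labs[i] == "PC") cdss[i, 1L] + 1L else lens[i]
          eg <- .examplePointerGrad(p, cfg, Xs[[i]], tix)
        } else {
          tg <- .TOK[.targetTokens(labs[i], prots[i], task)]
          N <- length(tg)
          w <- switch(task,
            class = 1,
            seq = rep(1 / N, N),
            seq_wt = positionWeights(N, objective$lambda))
          eg <- .exampleGrad(p, cfg, Xs[[i]], tg, w, objective$labelSmoothing)
        }
        if (!is.finite(eg$loss))
          stop("training diverged: non-finite loss at epoch ", ep)
        accum <- .addGrads(accum, eg$grads, 1 / length(b))
        tot <- tot + eg$loss; ntot <- ntot + 1L
      }
      nAcc <- nAcc + 1L
      if (nAcc >= plan$gradAccumSteps) {
        accum <- lapply(accum, function(x) x / nAcc)
        up <- .adamStep(p, accum, st, lrEp, weightDecay = weightDecay)
        p <- up$p; st <- up$st
        accum <- list(); nAcc <- 0L
      }
    }
    if (nAcc > 0L) {
      accum <- lapply(accum, function(x) x / nAcc)
      up <- .adamStep(p, accum, st, lrEp, weightDecay = weightDecay)
      p <- up$p; st <- up$st
    }
    mdl <- new("SeqModel", config = cfg, params = p)
    f1 <- NA_real_
    if (length(valIds)) {
      preds <- vapply(valIds, function(id) {
        s <- transcriptSeqs(transcripts)[[id]]
        mode <- if (task == "start") "pointer" else "first_token"
        classify(mdl, s, mode = mode)$label
      }, "")
      truth <- transcriptLabels(transcripts)[valIds]
      f1 <- confusionMetrics(preds, truth)$F1
      if (is.finite(f1) && f1 >= bestF1) { bestF1 <- f1; bestP <- p }
    } else bestP <- p
    log <- rbind(log, data.frame(epoch = epoch0 + ep, loss = tot / ntot,
                                 val_F1 = f1))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val_F1 %s", epoch0 + ep,
                      tot / ntot, format(f1, digits = 3)))
  }
  list(model = new("SeqModel", config = cfg, params = bestP),
       config = cfg, params = p, opt = st, log = log,
       rng = get(".Random.seed", envir = globalenv()))
}
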