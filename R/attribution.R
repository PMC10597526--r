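# Mutation-effect prediction: saturated in silico mutagenesis and its
# gradient-based approximations.  All methods share the scalar score
# S = l_<PC> - l_<NC> and produce L x 3 delta-S matrices with columns
# ordered alphabetically over the non-endogenous bases at each position.

# A scorer is either a SeqModel or a list(score = function(X) scalar,
# grad = function(X) L x 4 matrix); the latter admits closed-form oracles.
.asScorer <- function(x) {
  if (is(x, "SeqModel")) {
    list(score = function(X) .scoreForward(x, X)$S,
         grad = function(X) .scoreForward(x, X, wantGrad = TRUE)$dX,
         id = "SeqModel")
  } else if (is.list(x) && is.function(x$score)) {
    if (is.null(x$id)) x$id <- "scorer"
    x
  } else stop("expected a SeqModel or a list(score=, grad=) scorer")
}

.altBases <- function(ref) lapply(ref, function(r) sort(setdiff(RNA_BASES, r)))

.newMEM <- function(values, sequence, method, modelId,
                    beta = NA_real_, steps = NA_real_) {
  new("MutationEffectMatrix", values = values, refSequence = sequence,
      method = method, beta = beta, steps = steps, modelId = modelId)
}

#' Saturated in silico mutagenesis
#'
#' Evaluates the coding score of every single-base variant (3L model
#' evaluations for length L) and reports \eqn{\Delta S = S(variant) -
#' S(wild type)}.
#'
#' @param scorer a \code{\link{SeqModel}} or a
#'   \code{list(score=, grad=)} scorer over dense L x 4 inputs.
#' @param sequence wild-type RNA sequence.
#' @return a \code{\link{MutationEffectMatrix}} with method \code{"ism"}.
#' @export
ism <- function(scorer, sequence) {
  sc <- .asScorer(scorer)
  X <- seqToOneHot(sequence)
  S0 <- sc$score(X)
  L <- nrow(X)
  ref <- strsplit(sequence, "")[[1L]]
  alts <- .altBases(ref)
  vals <- matrix(0, L, 3L)
  for (i in seq_len(L)) {
    j <- match(ref[i], RNA_BASES)
    for (k in 1:3) {
      b <- match(alts[[i]][k], RNA_BASES)
      Xv <- X
      Xv[i, j] <- 0; Xv[i, b] <- 1
      vals[i, k] <- sc$score(Xv) - S0
    }
  }
  .newMEM(vals, sequence, "ism", sc$id)
}

#' Input gradient of the coding score
#'
#' One forward/backward pass; the gradient is taken with respect to the
#' one-hot coordinates through the linear embedding.
#'
#' @inheritParams ism
#' @return numeric L x 4 matrix (columns A, C, G, U).
#' @export
inputGradient <- function(scorer, sequence) {
  sc <- .asScorer(scorer)
  g <- sc$grad(seqToOneHot(sequence))
  colnames(g) <- RNA_BASES
  g
}

#' First-order Taylor approximation of mutation effects
#'
#' Pairs gradient columns: \eqn{\Delta S(i, j \to b) \approx \partial
#' S/\partial x_{ib} - \partial S/\partial x_{ij}}.  All 3L values come
#' from a single gradient evaluation.
#'
#' @param gradientMatrix L x 4 matrix from \code{\link{inputGradient}}.
#' @param sequence the wild-type sequence the gradient was taken at.
#' @param modelId scorer identifier for provenance.
#' @return a \code{\link{MutationEffectMatrix}} with method
#'   \code{"taylor"}.
#' @export
taylorApprox <- function(gradientMatrix, sequence, modelId = "scorer") {
  ref <- strsplit(sequence, "")[[1L]]
  alts <- .altBases(ref)
  L <- length(ref)
  vals <- matrix(0, L, 3L)
  for (i in seq_len(L)) {
    j <- match(ref[i], RNA_BASES)
    b <- match(alts[[i]], RNA_BASES)
    vals[i, ] <- gradientMatrix[i, b] - gradientMatrix[i, j]
  }
  .newMEM(vals, sequence, "taylor", modelId)
}

#' Integrated Gradients along a straight path
#'
#' Midpoint-rule approximation of the path integral of input gradients
#' from \code{baseline} to \code{x}; attributions are \eqn{(x - x')}
#' times the path-averaged gradient.  The completeness residual
#' \eqn{|\sum IG - (S(x) - S(x'))|} is reported alongside and shrinks as
#' \code{steps} grows.
#'
#' @param scorer scorer as in \code{\link{ism}}.
#' @param x dense L x 4 input matrix.
#' @param baseline dense L x 4 baseline matrix of the same shape.
#' @param steps number of integration steps (>= 1).
#' @return list with \code{attributions} (L x 4), \code{avgGrad} (L x 4),
#'   and \code{residual}.
#' @export
integratedGradients <- function(scorer, x, baseline, steps = 8L) {
  if (steps < 1L) stop("steps must be >= 1")
  sc <- .asScorer(scorer)
  if (!all(dim(x) == dim(baseline))) stop("baseline shape mismatch")
  avg <- matrix(0, nrow(x), ncol(x))
  for (m in seq_len(steps)) {
    a <- (m - 0.5) / steps
    avg <- avg + sc$grad(baseline + a * (x - baseline))
  }
  avg <- avg / steps
  attr <- (x - baseline) * avg
  res <- abs(sum(attr) - (sc$score(x) - sc$score(baseline)))
  list(attributions = attr, avgGrad = avg, residual = res)
}

#' Mutation effects from a single uniform-baseline IG run
#'
#' One Integrated Gradients evaluation along the path from the wild type
#' toward the uniform composition [0.25, 0.25, 0.25, 0.25] (the baseline
#' reframed as the destination), paired per position into \eqn{\Delta S}
#' estimates.  The default pairing subtracts the path-averaged gradients
#' of the alternative and endogenous bases, which recovers ISM exactly on
#' a linear scorer; \code{pairing = "attribution"} instead subtracts the
#' displacement-weighted attributions as sometimes written, which scales
#' the two terms unequally (see the methods vignette).
#'
#' @inheritParams ism
#' @param steps IG integration steps.
#' @param pairing \code{"avg_gradient"} (default) or
#'   \code{"attribution"}.
#' @return a \code{\link{MutationEffectMatrix}} with method
#'   \code{"ig_uniform"}.
#' @export
igUniformIsm <- function(scorer, sequence, steps = 8L,
                         pairing = c("avg_gradient", "attribution")) {
  pairing <- match.arg(pairing)
  sc <- .asScorer(scorer)
  X <- seqToOneHot(sequence)
  U <- matrix(0.25, nrow(X), 4L)
  ig <- integratedGradients(sc, U, X, steps)   # destination U, source x
  M <- if (pairing == "avg_gradient") ig$avgGrad else ig$attributions
  ref <- strsplit(sequence, "")[[1L]]
  alts <- .altBases(ref)
  vals <- matrix(0, nrow(X), 3L)
  for (i in seq_len(nrow(X))) {
    j <- match(ref[i], RNA_BASES)
    b <- match(alts[[i]], RNA_BASES)
    vals[i, ] <- M[i, b] - M[i, j]
  }
  .newMEM(vals, sequence, "ig_uniform", sc$id, steps = steps)
}

#' Mutation-Directed Integrated Gradients
#'
#' For each base b, one IG run against the baseline \eqn{X(b, \beta) =
#' \beta \cdot poly(b) + (1 - \beta) x} (a homopolymer pulled toward the
#' wild type); entries are combined as \eqn{IG_{ib} + IG_{ij}}, whose
#' displacement signs make the sum a difference of path-averaged
#' gradients scaled by \eqn{\beta}.  Four IG evaluations total.
#'
#' @inheritParams ism
#' @param beta path-truncation parameter in (0, 1].
#' @param steps IG integration steps per baseline (default 8).
#' @param sign \code{"plus"} combines per the displacement convention
#'   above; \code{"minus"} is the alternative pairing kept for the sign
#'   diagnostic.
#' @return a \code{\link{MutationEffectMatrix}} with method
#'   \code{"mdig"}.
#' @export
mdig <- function(scorer, sequence, beta = 0.25, steps = 8L,
                 sign = c("plus", "minus")) {
  sign <- match.arg(sign)
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  sc <- .asScorer(scorer)
  X <- seqToOneHot(sequence)
  L <- nrow(X)
  ref <- strsplit(sequence, "")[[1L]]
  refIdx <- match(ref, RNA_BASES)
  alts <- .altBases(ref)
  vals <- matrix(0, L, 3L)
  for (bi in 1:4) {
    poly <- matrix(0, L, 4L); poly[, bi] <- 1
    Xb <- beta * poly + (1 - beta) * X
    ig <- integratedGradients(sc, Xb, X, steps)  # destination X(b, beta)
    A <- ig$attributions
    for (i in seq_len(L)) {
      j <- refIdx[i]
      if (bi == j) next
      k <- match(RNA_BASES[bi], alts[[i]])
      vals[i, k] <- if (sign == "plus") A[i, bi] + A[i, j]
                    else A[i, bi] - A[i, j]
    }
  }
  .newMEM(vals, sequence, "mdig", sc$id, beta = beta, steps = steps)
}

#' Tune the MDIG beta parameter against ISM
#'
#' Evaluates a beta grid on validation sequences and selects the value
#' maximizing the median per-transcript Pearson correlation with ISM.
#'
#' @inheritParams ism
#' @param sequences character vector of validation sequences.
#' @param ismList optional precomputed list of ISM matrices (one per
#'   sequence); computed when missing.
#' @param grid candidate beta values.
#' @param steps IG steps per baseline.
#' @return list with \code{beta} (selected), and \code{table}
#'   (data.frame beta / median_r).
#' @export
tuneMdigBeta <- function(scorer, sequences, ismList = NULL,
                         grid = c(0.05, 0.1, 0.25, 0.5, 1.0), steps = 8L) {
  if (is.null(ismList)) ismList <- lapply(sequences, function(s) ism(scorer, s))
  med <- vapply(grid, function(b) {
    rs <- mapply(function(s, im)
      pearsonFlat(mdig(scorer, s, beta = b, steps = steps), im),
      sequences, ismList)
    stats::median(rs, na.rm = TRUE)
  }, 0)
  list(beta = grid[which.max(med)],
       table = data.frame(beta = grid, median_r = med))
}

# Agreement metrics ------------------------------------------------------

.memValues <- function(x) if (is(x, "MutationEffectMatrix")) x@values else x

#' Pearson correlation over flattened mutation-effect matrices
#'
#' @param m1,m2 \code{MutationEffectMatrix} objects or plain matrices of
#'   equal shape.
#' @export
pearsonFlat <- function(m1, m2) {
  stats::cor(as.vector(.memValues(m1)), as.vector(.memValues(m2)))
}

#' Median position-wise cosine similarity
#'
#' Cosine similarity of the per-position substitution-score vectors,
#' summarized by the median over positions (rank-free comparison that
#' ignores the relative scaling of positions).  Zero-norm rows are
#' skipped.
#'
#' @inheritParams pearsonFlat
#' @export
medianPositionwiseCosine <- function(m1, m2) {
  a <- .memValues(m1); b <- .memValues(m2)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  ok <- na > 0 & nb > 0
  stats::median(rowSums(a * b)[ok] / (na[ok] * nb[ok]))
}

#' Inter-replicate agreement of mutation-effect predictions
#'
#' Mean of the chosen metric over all unordered pairs of replicates for
#' one transcript.
#'
#' @param matrices list of mutation-effect matrices, one per replicate.
#' @param metric \code{"pearson"} or \code{"cosine"}.
#' @export
interReplicateAgreement <- function(matrices, metric = c("pearson", "cosine")) {
  metric <- match.arg(metric)
  f <- if (metric == "pearson") pearsonFlat else medianPositionwiseCosine
  n <- length(matrices)
  if (n < 2L) stop("need at least two replicates")
  prs <- utils::combn(n, 2L)
  mean(apply(prs, 2L, function(ij) f(matrices[[ij[1L]]], matrices[[ij[2L]]])))
}

#' Agreement of an approximation with ISM (intra-replicate)
#'
#' Mean of the metric over matched replicate pairs: replicate i's
#' approximation is compared with replicate i's ISM.
#'
#' @param ismMatrices,approxMatrices lists of matrices, matched by
#'   replicate.
#' @param metric \code{"pearson"} or \code{"cosine"}.
#' @export
agreementWithIsm <- function(ismMatrices, approxMatrices,
                             metric = c("pearson", "cosine")) {
  metric <- match.arg(metric)
  f <- if (metric == "pearson") pearsonFlat else medianPositionwiseCosine
  stopifnot(length(ismMatrices) == length(approxMatrices))
  mean(mapply(f, ismMatrices, approxMatrices))
}

#' Diagnose the MDIG pairing sign
#'
#' Computes MDIG under both pairing conventions and reports which
#' correlates better with ISM on the given sequences.
#'
#' @inheritParams tuneMdigBeta
#' @param beta MDIG beta.
#' @return list with per-sign median correlations and the better sign.
#' @export
mdigSignDiagnostic <- function(scorer, sequences, ismList = NULL,
                               beta = 0.25, steps = 8L) {
  if (is.null(ismList)) ismList <- lapply(sequences, function(s) ism(scorer, s))
  med <- vapply(c("plus", "minus"), function(sg) {
    rs <- mapply(function(s, im)
      pearsonFlat(mdig(scorer, s, beta = beta, steps = steps, sign = sg), im),
      sequences, ismList)
    stats::median(rs, na.rm = TRUE)
  }, 0)
  list(plus = med[["plus"]], minus = med[["minus"]],
       better = names(med)[which.max(med)])
}
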