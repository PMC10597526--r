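# Classification ---------------------------------------------------------

#' Classify a transcript as protein-coding or noncoding
#'
#' \code{first_token} mode reads the class-token logits at the first
#' decoding step: \eqn{S = l_{PC} - l_{NC}} and \eqn{p_{PC}} is the
#' two-token softmax.  \code{pointer} mode (for start-task models) sums
#' the pointer probabilities of all positions before the last; a
#' prediction is NC when the argmax is the final position.
#'
#' @param model a \code{\link{SeqModel}}.
#' @param sequence character RNA sequence.
#' @param mode \code{"first_token"} or \code{"pointer"}.
#' @return list with \code{label} ("PC"/"NC"), \code{S} (logit
#'   difference) and \code{p_pc}.
#' @export
classify <- function(model, sequence, mode = c("first_token", "pointer")) {
  mode <- match.arg(mode)
  H <- encode(model, sequence)
  if (mode == "first_token") {
    st <- decodeStep(model, "<s>", H)
    lpc <- st$logits[["<PC>"]]; lnc <- st$logits[["<NC>"]]
    S <- lpc - lnc
    p_pc <- 1 / (1 + exp(-S))
    list(label = if (S >= 0) "PC" else "NC", S = S, p_pc = p_pc)
  } else {
    pr <- pointerForward(model, H)
    L <- length(pr)
    p_pc <- sum(pr[-L])
    eps <- 1e-12
    S <- log(max(p_pc, eps)) - log(max(1 - p_pc, eps))
    list(label = if (which.max(pr) == L) "NC" else "PC", S = S, p_pc = p_pc)
  }
}

# Beam search ------------------------------------------------------------

#' Beam-search decoding of the output sequence
#'
#' Standard beam expansion over the output vocabulary starting from
#' \code{<s>}; hypotheses completed by \code{</s>} (or by reaching
#' \code{maxLen}) are ranked by length-normalized score
#' \eqn{\log P / T^\alpha}.  All beams are returned, exposing the
#' lower-ranked decodings (for correctly classified noncoding transcripts
#' these typically begin with \code{<PC>} and carry candidate peptides).
#'
#' @param model a \code{\link{SeqModel}}.
#' @param sequence character RNA sequence.
#' @param beamSize beam width (>= 1; 1 is greedy decoding).
#' @param alpha length-normalization exponent (0 ranks by raw log
#'   probability; default 0.6, the usual machine-translation setting).
#' @param maxLen maximum output length.
#' @return list of hypotheses ordered by normalized score, each a list
#'   with \code{tokens}, \code{rawLogProb}, \code{normalizedScore},
#'   \code{completed}, and \code{protein} (amino-acid tokens collapsed).
#' @export
beamSearch <- function(model, sequence, beamSize = 4L, alpha = 0.6,
                       maxLen = 200L) {
  if (beamSize < 1L) stop("beamSize must be >= 1")
  H <- encode(model, sequence)
  eosId <- .TOK[["<s>"]]
  live <- list(list(tokens = "<s>", lp = 0))
  done <- list()
  for (step in seq_len(maxLen)) {
    cand <- list()
    for (hyp in live) {
      st <- decodeStep(model, hyp$tokens, H)
      lg <- st$logits
      if (step > 1L) lg[c("<PC>", "<NC>")] <- -Inf  # class tokens lead only
      lg["<s>"] <- -Inf
      logp <- lg - (max(lg) + log(sum(exp(lg - max(lg)))))
      top <- order(logp, decreasing = TRUE)[seq_len(min(beamSize, sum(is.finite(logp))))]
      for (k in top)
        cand[[length(cand) + 1L]] <- list(tokens = c(hyp$tokens, names(.TOK)[k]),
                                          lp = hyp$lp + logp[k])
    }
    if (!length(cand)) break
    ord <- order(vapply(cand, function(h) h$lp, 0), decreasing = TRUE)
    cand <- cand[ord[seq_len(min(beamSize, length(cand)))]]
    live <- list()
    for (h in cand) {
      if (utils::tail(h$tokens, 1L) == "</s>") done[[length(done) + 1L]] <- h
      else live[[length(live) + 1L]] <- h
    }
    if (!length(live)) break
    if (length(done) >= beamSize) break
  }
  done <- c(done, live)
  hyps <- lapply(done, function(h) {
    toks <- h$tokens[-1L]
    outLen <- length(toks)
    ns <- if (outLen > 0) h$lp / outLen^alpha else h$lp
    aa <- toks[toks %in% AA_LETTERS]
    list(tokens = toks, rawLogProb = h$lp, normalizedScore = ns,
         completed = length(toks) > 0 && utils::tail(toks, 1L) == "</s>",
         protein = paste(aa, collapse = ""))
  })
  hyps[order(vapply(hyps, function(h) h$normalizedScore, 0), decreasing = TRUE)]
}

# CDS detection by global alignment --------------------------------------

#' Locate the CDS supported by a predicted protein
#'
#' Needleman-Wunsch global alignment of the predicted protein against the
#' translation of every sense ORF; the ORF with the highest percent
#' identity (matches / alignment length) wins, ties broken by 5'-most
#' start.  Default scoring: match 1, mismatch 0, gap -1, no affine
#' extension.
#'
#' @param predictedProtein amino-acid string from decoding.
#' @param sequence transcript RNA sequence.
#' @param annotatedCds optional length-2 vector (0-based half-open CDS)
#'   used to set the \code{isAnnotatedCds} flag.
#' @param match,mismatch,gap alignment scores.
#' @return list with \code{orf} (one-row data.frame), \code{identity} in
#'   [0, 1], \code{isAnnotatedCds}; or \code{NULL} when the transcript
#'   has no ORF or the prediction is empty.
#' @export
cdsDetect <- function(predictedProtein, sequence, annotatedCds = NULL,
                      match = 1, mismatch = 0, gap = -1) {
  orfs <- findOrfs(sequence)
  if (!nrow(orfs) || !nchar(predictedProtein)) return(NULL)
  ids <- vapply(orfs$protein, function(tr)
    alignmentIdentity(predictedProtein, tr, match, mismatch, gap), 0,
    USE.NAMES = FALSE)
  best <- order(-ids, orfs$start)[1L]
  isAnn <- !is.null(annotatedCds) && !anyNA(annotatedCds) &&
    orfs$start[best] == annotatedCds[1L] && orfs$end[best] == annotatedCds[2L]
  list(orf = orfs[best, , drop = FALSE], identity = ids[best],
       isAnnotatedCds = isAnn)
}

#' Percent identity of a global protein alignment
#'
#' @param a,b amino-acid strings.
#' @param match,mismatch,gap Needleman-Wunsch scores (gap is per-residue,
#'   no affine extension).
#' @return matches divided by alignment length.
#' @export
alignmentIdentity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  alph <- sort(unique(c(AA_LETTERS, strsplit(paste0(a, b), "")[[1L]], "*")))
  sub <- matrix(mismatch, length(alph), length(alph),
                dimnames = list(alph, alph))
  diag(sub) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sub, gapOpening = 0, gapExtension = -gap,
    type = "global")
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# Metrics ----------------------------------------------------------------

#' Binary classification metrics with PC as the positive class
#'
#' MCC uses the Matthews form (TP*TN - FP*FN over the geometric mean of
#' the marginals); a degenerate denominator yields 0 by convention.
#'
#' @param predictions,labels character vectors of "PC"/"NC".
#' @return list with \code{F1}, \code{precision}, \code{recall},
#'   \code{MCC} and the confusion counts.
#' @export
confusionMetrics <- function(predictions, labels) {
  tp <- sum(predictions == "PC" & labels == "PC")
  tn <- sum(predictions == "NC" & labels == "NC")
  fp <- sum(predictions == "PC" & labels == "NC")
  fn <- sum(predictions == "NC" & labels == "PC")
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(F1 = f1, precision = prec, recall = rec, MCC = mcc,
       TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Area under the precision-recall curve
#'
#' Step integration over score thresholds (the average-precision form:
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over descending scores).
#'
#' @param scores numeric scores, higher meaning more likely PC.
#' @param labels character "PC"/"NC".
#' @export
auprc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord] == "PC"
  npos <- sum(y)
  if (npos == 0) return(NA_real_)
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}
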