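#' Default codon-usage bias for the synthetic generator
#'
#' Per amino acid, codon probabilities skewed by the third codon position:
#' codons ending in C are strongly favored and codons ending in U
#' disfavored.  This plants a known synonymous-codon signal (and with it a
#' strong 3-nt periodicity) in generated coding regions, so that models
#' and attribution methods have a recoverable target.
#'
#' @return named list: amino acid -> named probability vector over codons.
#' @export
defaultCodonBias <- function() {
  gc <- Biostrings::RNA_GENETIC_CODE
  gc <- gc[gc != "*"]
  third_w <- c(A = 2, C = 6, G = 2, U = 0.4)
  out <- list()
  for (aa in unique(gc)) {
    codons <- names(gc)[gc == aa]
    w <- third_w[substr(codons, 3, 3)]
    out[[aa]] <- stats::setNames(as.numeric(w / sum(w)), codons)
  }
  out
}

#' Parameters of the synthetic transcriptome generator
#'
#' Defines the desk-scale corpus the models are trained and evaluated on:
#' balanced mRNA/lncRNA classes with matched length distributions, mRNAs
#' built as 5'UTR + AUG-initiated CDS (Kozak-like context, biased codon
#' usage, in-frame stop) + 3'UTR, and lncRNAs lacking a genuine long ORF.
#' In hard mode lncRNAs carry a long spurious ORF with uniform codon usage
#' and no Kozak context, so longest-ORF length alone no longer separates
#' the classes.
#'
#' @param nPerClass transcripts per class.
#' @param lengthRange total transcript length bounds in nt (max 1200).
#' @param codonBias amino acid -> codon probability mapping.
#' @param kozakStrength probability of G at position +1 after the start
#'   codon (the first base of the first internal codon).
#' @param utrGC GC fraction of UTR base composition.
#' @param spuriousOrfMaxCodons cap on lncRNA ORF length in codons
#'   (stop codon included); must stay well below typical mRNA CDS length
#'   so the classes remain separable in principle.
#' @param hard logical; enable hard-mode lncRNAs (long unbiased ORFs).
#' @param seed integer seed used by \code{\link{generateDataset}}.
#' @return validated parameter list of class \code{GeneratorParams}.
#' @export
generatorParams <- function(nPerClass = 500L, lengthRange = c(120L, 360L),
                            codonBias = defaultCodonBias(),
                            kozakStrength = 0.85, utrGC = 0.5,
                            spuriousOrfMaxCodons = 12L, hard = FALSE,
                            seed = 1L) {
  stopifnot(length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2],
            lengthRange[2] <= 1200L, kozakStrength >= 0, kozakStrength <= 1,
            utrGC > 0, utrGC < 1)
  for (aa in names(codonBias)) {
    if (abs(sum(codonBias[[aa]]) - 1) > 1e-8)
      stop("codon probabilities for ", aa, " do not sum to 1")
  }
  min_cds_codons <- floor((lengthRange[1] - 2 * .MIN_UTR - 6) / 3)
  if (min_cds_codons < 5L)
    stop("lengthRange too small to fit a 5'UTR, CDS and 3'UTR")
  if (!hard && spuriousOrfMaxCodons >= min_cds_codons)
    warning("spurious ORF cap is not clearly below typical CDS length; ",
            "classes may not be separable by ORF length")
  structure(list(nPerClass = as.integer(nPerClass),
                 lengthRange = as.integer(lengthRange),
                 codonBias = codonBias, kozakStrength = kozakStrength,
                 utrGC = utrGC,
                 spuriousOrfMaxCodons = as.integer(spuriousOrfMaxCodons),
                 hard = hard, seed = as.integer(seed)),
            class = "GeneratorParams")
}

.MIN_UTR <- 8L

.sampleUtr <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.sampleCodons <- function(nCodons, bias, kozakStrength) {
  aas <- sample(names(bias), nCodons, replace = TRUE)
  codons <- vapply(aas, function(aa)
    sample(names(bias[[aa]]), 1L, prob = bias[[aa]]), "")
  if (nCodons >= 1L && stats::runif(1) < kozakStrength) {
    # Kozak-like context: force G at +1 relative to the start codon
    g_first <- lapply(bias, function(p) p[substr(names(p), 1, 1) == "G"])
    g_first <- g_first[vapply(g_first, length, 1L) > 0]
    aa <- sample(names(g_first), 1L)
    p <- g_first[[aa]]
    codons[1L] <- sample(names(p), 1L, prob = p / sum(p))
  }
  codons
}

.mrnaLayout <- function(L, lengthRange) {
  # allocate total length L over 5'UTR / CDS / 3'UTR
  utr5 <- sample(.MIN_UTR:max(.MIN_UTR, round(0.2 * L)), 1L)
  utr3_t <- sample(.MIN_UTR:max(.MIN_UTR, round(0.2 * L)), 1L)
  nCod <- floor((L - utr5 - utr3_t - 6L) / 3L)
  utr3 <- L - utr5 - 6L - 3L * nCod
  list(utr5 = utr5, utr3 = utr3, nCodons = nCod)
}

#' Generate one synthetic mRNA
#'
#' Draws from the current RNG state; seed control belongs to the caller
#' (\code{\link{generateDataset}} seeds once per corpus).
#'
#' @param params a \code{\link{generatorParams}} object.
#' @param id record id.
#' @return a one-record \code{\link{TranscriptSet}} with consistent
#'   \code{cds} and \code{protein} fields.
#' @export
generateMrna <- function(params, id = "PC_1") {
  L <- sample(params$lengthRange[1]:params$lengthRange[2], 1L)
  lay <- .mrnaLayout(L, params$lengthRange)
  if (lay$nCodons < 5L)
    stop("infeasible length constraints: CDS would have <5 codons")
  codons <- .sampleCodons(lay$nCodons, params$codonBias, params$kozakStrength)
  stopc <- sample(STOP_CODONS, 1L)
  cds <- paste0("AUG", paste(codons, collapse = ""), stopc)
  seqs <- paste0(.sampleUtr(lay$utr5, params$utrGC), cds,
                 .sampleUtr(lay$utr3, params$utrGC))
  cds_start <- lay$utr5
  cds_end <- cds_start + nchar(cds)
  prot <- translateRNA(substr(seqs, cds_start + 1L, cds_end - 3L))
  transcriptSet(id, seqs, "PC", cdsStart = cds_start, cdsEnd = cds_end,
                protein = prot)
}

#' Generate one synthetic lncRNA
#'
#' Default mode: random sequence with UTR base composition; any ORF longer
#' than \code{spuriousOrfMaxCodons} codons is destroyed by converting one
#' of its internal codons into a stop, leaving only spurious short ORFs.
#' Hard mode: built like an mRNA (long AUG-initiated ORF) but with uniform
#' codon usage and no Kozak context, and no CDS annotation.
#'
#' @inheritParams generateMrna
#' @param budget maximum ORF-breaking iterations before giving up.
#' @export
generateLncrna <- function(params, id = "NC_1", budget = 200L) {
  L <- sample(params$lengthRange[1]:params$lengthRange[2], 1L)
  if (params$hard) {
    lay <- .mrnaLayout(L, params$lengthRange)
    uniform <- lapply(params$codonBias, function(p)
      stats::setNames(rep(1 / length(p), length(p)), names(p)))
    codons <- .sampleCodons(lay$nCodons, uniform, kozakStrength = 0)
    seqs <- paste0(.sampleUtr(lay$utr5, params$utrGC),
                   "AUG", paste(codons, collapse = ""),
                   sample(STOP_CODONS, 1L),
                   .sampleUtr(lay$utr3, params$utrGC))
    return(transcriptSet(id, seqs, "NC"))
  }
  seqs <- .sampleUtr(L, params$utrGC)
  cap_nt <- 3L * params$spuriousOrfMaxCodons
  for (iter in seq_len(budget)) {
    orf <- longestOrf(seqs)
    if (is.null(orf) || (orf$end - orf$start) <= cap_nt)
      return(transcriptSet(id, seqs, "NC"))
    # break the ORF: replace an internal codon with a stop codon
    ncod <- (orf$end - orf$start) / 3L
    k <- sample(2:(ncod - 1L), 1L)
    at <- orf$start + 3L * (k - 1L)
    substr(seqs, at + 1L, at + 3L) <- sample(STOP_CODONS, 1L)
  }
  stop("generateLncrna: ORF-breaking budget exceeded (sequence length ", L,
       ", cap ", params$spuriousOrfMaxCodons, " codons)")
}

#' Generate a balanced synthetic transcriptome with splits
#'
#' Seeds the RNG from \code{params$seed}, generates \code{nPerClass}
#' mRNAs and lncRNAs, and partitions them with \code{\link{makeSplits}}.
#'
#' @param params a \code{\link{generatorParams}} object.
#' @param fractions split fractions passed to \code{\link{makeSplits}}.
#' @param fastaPath,annotationPath optional output paths; when given the
#'   corpus is also written in \code{\link{writeTranscripts}} format.
#' @return list with elements \code{transcripts} (a
#'   \code{\link{TranscriptSet}}) and \code{split} (a
#'   \code{\link{DatasetSplit}}).
#' @export
generateDataset <- function(params, fractions = c(0.8, 0.1, 0.1),
                            fastaPath = NULL, annotationPath = NULL) {
  set.seed(params$seed)
  n <- params$nPerClass
  recs <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    recs[[i]] <- generateMrna(params, sprintf("PC_%04d", i))
    recs[[n + i]] <- generateLncrna(params, sprintf("NC_%04d", i))
  }
  ts <- do.call(.bindTranscriptSets, recs)
  split <- makeSplits(ts, fractions, seed = params$seed)
  if (!is.null(fastaPath)) writeTranscripts(ts, fastaPath, annotationPath)
  list(transcripts = ts, split = split)
}

.bindTranscriptSets <- function(...) {
  parts <- list(...)
  seqs <- do.call(c, lapply(parts, function(p) p@seqs))
  new("TranscriptSet",
      seqs = seqs,
      label = unlist(lapply(parts, function(p) p@label)),
      cds = do.call(rbind, lapply(parts, function(p) p@cds)),
      protein = unlist(lapply(parts, function(p) p@protein)),
      nonAUG = unlist(lapply(parts, function(p) p@nonAUG)))
}

#' Longest-ORF-length threshold classifier
#'
#' Sanity baseline: predicts PC when the longest ORF exceeds
#' \code{thresholdNt} nucleotides.  On default generator settings this
#' separates the classes almost perfectly; on hard-mode data it degrades,
#' demonstrating that more than ORF length is needed there.
#'
#' @param x a \code{TranscriptSet}.
#' @param thresholdNt decision threshold on longest-ORF length (nt).
#' @return character vector of predicted labels.
#' @export
orfLengthClassifier <- function(x, thresholdNt = 90L) {
  vapply(transcriptSeqs(x), function(s) {
    o <- longestOrf(s)
    if (!is.null(o) && (o$end - o$start) > thresholdNt) "PC" else "NC"
  }, "")
}
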