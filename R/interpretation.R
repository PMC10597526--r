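# Importance tracks, metagenes, motif-window extraction and perturbation
# experiments built on mutation-effect matrices.

#' Counterfactual-class importance track
#'
#' Under \code{up_PC}, the importance of position i is the strongest push
#' toward the noncoding class achievable by mutating it: \eqn{\max_b
#' (-\Delta S_{ib})} clipped at 0.  \code{up_NC} is symmetric with
#' \eqn{+\Delta S}.
#'
#' @param mem a \code{\link{MutationEffectMatrix}}.
#' @param direction \code{"up_PC"} or \code{"up_NC"}.
#' @return an \code{\link{ImportanceTrack}} with an all-FALSE mask.
#' @export
importanceTrack <- function(mem, direction = c("up_PC", "up_NC")) {
  direction <- match.arg(direction)
  v <- if (direction == "up_PC") apply(-mem@values, 1L, max)
       else apply(mem@values, 1L, max)
  new("ImportanceTrack", values = pmax(v, 0), direction = direction,
      mask = rep(FALSE, nrow(mem@values)))
}

# which alternative base the track's direction selects at each position
.selectedMutation <- function(mem, direction) {
  k <- if (direction == "up_PC") apply(-mem@values, 1L, which.max)
       else apply(mem@values, 1L, which.max)
  ref <- strsplit(mem@refSequence, "")[[1L]]
  alts <- .altBases(ref)
  vapply(seq_along(ref), function(i) alts[[i]][k[i]], "")
}

#' Mask canonical ORF signals in an importance track
#'
#' Masks the start- and stop-codon positions of the annotated CDS (or the
#' longest ORF for records without one) and every position whose selected
#' strongest mutation would create a premature in-frame stop codon, so
#' that downstream maxima reveal signals beyond the dominant ORF
#' boundary features.
#'
#' @param track an \code{\link{ImportanceTrack}}.
#' @param sequence the transcript RNA sequence.
#' @param mem the \code{\link{MutationEffectMatrix}} the track came from.
#' @param cds optional 0-based half-open CDS (length-2); the longest ORF
#'   is used when absent.
#' @return the track with an updated mask (an ORF-less transcript gets an
#'   empty mask).
#' @export
maskCanonical <- function(track, sequence, mem, cds = NULL) {
  L <- length(track@values)
  mask <- rep(FALSE, L)
  span <- if (!is.null(cds) && !anyNA(cds)) cds else {
    o <- longestOrf(sequence)
    if (is.null(o)) NULL else c(o$start, o$end)
  }
  if (!is.null(span)) {
    mask[(span[1L] + 1L):(span[1L] + 3L)] <- TRUE   # start codon
    mask[(span[2L] - 2L):span[2L]] <- TRUE          # stop codon
    sel <- .selectedMutation(mem, track@direction)
    ch <- strsplit(sequence, "")[[1L]]
    for (i in seq.int(span[1L] + 1L, span[2L] - 3L)) {   # CDS minus stop, 1-based
      ci <- (i - 1L - span[1L]) %/% 3L                   # codon index from 0
      cs <- span[1L] + 3L * ci                           # codon start, 0-based
      cod <- ch[(cs + 1L):(cs + 3L)]
      if (paste(cod, collapse = "") %in% STOP_CODONS) next
      cod[i - cs] <- sel[i]
      if (paste(cod, collapse = "") %in% STOP_CODONS) mask[i] <- TRUE
    }
  }
  new("ImportanceTrack", values = track@values, direction = track@direction,
      mask = mask)
}

#' Partition a transcript into functional regions
#'
#' mRNAs: 5'UTR / CDS / 3'UTR from the annotated CDS; noncoding records:
#' upstream / ORF / downstream demarcated by the longest ORF (the whole
#' transcript is "upstream" when no ORF exists).  Intervals are 0-based
#' half-open, disjoint, ordered, and cover the sequence.
#'
#' @param sequence RNA sequence.
#' @param cds optional 0-based half-open CDS.
#' @return data.frame with columns \code{region}, \code{start},
#'   \code{end}.
#' @export
regionPartition <- function(sequence, cds = NULL) {
  L <- nchar(sequence)
  if (!is.null(cds) && !anyNA(cds)) {
    df <- data.frame(region = c("utr5", "cds", "utr3"),
                     start = c(0L, cds[1L], cds[2L]),
                     end = c(cds[1L], cds[2L], L))
  } else {
    o <- longestOrf(sequence)
    if (is.null(o))
      return(data.frame(region = "upstream", start = 0L, end = L))
    df <- data.frame(region = c("upstream", "orf", "downstream"),
                     start = c(0L, o$start, o$end),
                     end = c(o$start, o$end, L))
  }
  df[df$end > df$start, , drop = FALSE]
}

#' Anchored metagene of per-position signals
#'
#' Aligns each series at its anchor, averages per relative position, and
#' drops positions contributed by fewer than \code{coverageThreshold} of
#' the series.
#'
#' @param seriesList list of numeric vectors.
#' @param anchors integer vector of 0-based anchor positions, one per
#'   series.
#' @param coverageThreshold minimum fraction of series covering a
#'   relative position (default 0.70).
#' @param anchor label describing the anchor.
#' @return a \code{\link{MetageneProfile}}.
#' @export
metagene <- function(seriesList, anchors, coverageThreshold = 0.70,
                     anchor = "start_codon") {
  stopifnot(length(seriesList) == length(anchors))
  n <- length(seriesList)
  rel_min <- min(-anchors)
  rel_max <- max(vapply(seriesList, length, 1L) - 1L - anchors)
  pos <- rel_min:rel_max
  sums <- numeric(length(pos)); cnt <- numeric(length(pos))
  for (k in seq_len(n)) {
    rel <- seq_along(seriesList[[k]]) - 1L - anchors[k]
    ix <- match(rel, pos)
    sums[ix] <- sums[ix] + seriesList[[k]]
    cnt[ix] <- cnt[ix] + 1
  }
  keep <- cnt / n >= coverageThreshold
  new("MetageneProfile", position = as.integer(pos[keep]),
      mean = sums[keep] / cnt[keep], coverage = cnt[keep] / n,
      anchor = anchor)
}

#' Binned metagene of absolute mutation effects
#'
#' Per transcript, positions are mapped to \code{nBins} equal-width bins
#' over the given span (whole transcript by default); \eqn{|\Delta S|} is
#' averaged over the three substitutions, within bins, then across
#' transcripts.
#'
#' @param memList list of \code{\link{MutationEffectMatrix}} objects.
#' @param nBins number of positional bins (default 25).
#' @param spans optional list of 0-based half-open \code{c(start, end)}
#'   spans to bin over (one per matrix); whole transcript when NULL.
#' @return a \code{\link{MetageneProfile}} with bin indices as positions.
#' @export
binnedMetagene <- function(memList, nBins = 25L, spans = NULL) {
  acc <- matrix(0, 0L, nBins)
  for (k in seq_along(memList)) {
    mem <- memList[[k]]
    v <- rowMeans(abs(mem@values))
    span <- if (is.null(spans)) c(0L, length(v)) else spans[[k]]
    ix <- seq.int(span[1L] + 1L, span[2L])
    bins <- pmin(((ix - 1L - span[1L]) * nBins) %/% (span[2L] - span[1L]),
                 nBins - 1L)
    m <- vapply(0:(nBins - 1L), function(b) mean(v[ix[bins == b]]), 0)
    acc <- rbind(acc, m)
  }
  new("MetageneProfile", position = 0:(nBins - 1L),
      mean = colMeans(acc), coverage = colMeans(!is.na(acc)),
      anchor = "binned")
}

# Motif windows ----------------------------------------------------------

#' Extract importance-centered motif windows
#'
#' For each transcript x region, a window of \code{flank} nt on each side
#' of the unmasked importance argmax (21 nt total by default) is
#' extracted for motif discovery.  Ties break to the 5'-most position.
#' Windows truncated by the region boundary (fewer than 2*flank+1
#' retained positions after clipping) are skipped and logged.
#'
#' @param tracks named list of \code{\link{ImportanceTrack}} objects
#'   (names are transcript ids).
#' @param sequences named character vector of the matching RNA sequences.
#' @param partitions named list of \code{\link{regionPartition}} frames.
#' @param flank half-window in nt (default 10).
#' @return data.frame with columns \code{id}, \code{region},
#'   \code{direction}, \code{center}, \code{start}, \code{end},
#'   \code{seq}; skipped records are reported in the
#'   \code{"skipped"} attribute.
#' @export
extractMotifWindows <- function(tracks, sequences, partitions, flank = 10L) {
  rows <- list(); skipped <- character(0)
  wlen <- 2L * flank + 1L
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    s <- sequences[[id]]
    part <- partitions[[id]]
    for (r in seq_len(nrow(part))) {
      a <- part$start[r]; b <- part$end[r]          # 0-based half-open
      if (b - a < wlen) {
        skipped <- c(skipped, sprintf("%s/%s: region shorter than %d nt",
                                      id, part$region[r], wlen))
        next
      }
      ix <- (a + 1L):b
      vals <- tr@values[ix]
      vals[tr@mask[ix]] <- -Inf
      if (!any(is.finite(vals) & vals > -Inf)) next
      c0 <- a + which.max(vals) - 1L                # 0-based argmax; ties 5'-most
      ws <- c0 - flank; we <- c0 + flank            # inclusive 0-based
      if (ws < a || we > b - 1L) {
        skipped <- c(skipped, sprintf("%s/%s: window clipped at region boundary",
                                      id, part$region[r]))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, region = part$region[r], direction = tr@direction,
        center = c0, start = ws, end = we + 1L,
        seq = substr(s, ws + 1L, we + 1L), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), region = character(0),
               direction = character(0), center = integer(0),
               start = integer(0), end = integer(0), seq = character(0))
  attr(out, "skipped") <- skipped
  out
}

#' Build a control window set for motif discovery
#'
#' Strategy 1: for each primary window, one window at a random position
#' from the same transcript and region, not overlapping the primary.
#' Strategy 2: the most important windows under the same importance
#' setting from the opposite RNA class (pass them as
#' \code{oppositeWindows}).
#'
#' @param primaries data.frame from \code{\link{extractMotifWindows}}.
#' @param sequences named character vector of transcript sequences.
#' @param partitions named list of region partitions.
#' @param strategy 1 or 2.
#' @param oppositeWindows for strategy 2, the opposite class's window
#'   set.
#' @param flank half-window in nt.
#' @return data.frame in the same format as the primary set.
#' @export
buildControlSet <- function(primaries, sequences, partitions, strategy = 1L,
                            oppositeWindows = NULL, flank = 10L) {
  if (strategy == 2L) {
    if (is.null(oppositeWindows))
      stop("strategy 2 requires the opposite class's windows")
    return(oppositeWindows)
  }
  wlen <- 2L * flank + 1L
  rows <- list()
  for (r in seq_len(nrow(primaries))) {
    id <- primaries$id[r]
    part <- partitions[[id]]
    reg <- part[part$region == primaries$region[r], ]
    a <- reg$start; b <- reg$end
    centers <- (a + flank):(b - 1L - flank)
    # exclude any center whose window would overlap the primary window
    ok <- centers + flank < primaries$start[r] |
          centers - flank > primaries$end[r] - 1L
    centers <- centers[ok]
    if (!length(centers)) next
    c0 <- if (length(centers) == 1L) centers else sample(centers, 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, region = primaries$region[r], direction = primaries$direction[r],
      center = c0, start = c0 - flank, end = c0 + flank + 1L,
      seq = substr(sequences[[id]], c0 - flank + 1L, c0 + flank + 1L),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else primaries[0, ]
}

#' Write motif windows as FASTA for STREME-style tools
#'
#' @param windows data.frame from \code{\link{extractMotifWindows}}.
#' @param path output FASTA path.
#' @export
writeMotifFasta <- function(windows, path) {
  x <- Biostrings::RNAStringSet(windows$seq)
  names(x) <- sprintf("%s|%s|%s|%d", windows$id, windows$region,
                      windows$direction, windows$center)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Perturbations ----------------------------------------------------------

#' Dinucleotide-frequency-preserving shuffle
#'
#' Euler-path walk on the dinucleotide multigraph (Altschul-Erickson
#' style): the shuffled sequence has exactly the original dinucleotide
#' count vector and the original first and last characters.
#'
#' @param sequence character sequence (length >= 3 to shuffle).
#' @return shuffled sequence.
#' @export
dinucleotideShuffle <- function(sequence) {
  ch <- strsplit(sequence, "")[[1L]]
  n <- length(ch)
  if (n < 3L) return(sequence)
  verts <- unique(ch)
  adj <- lapply(stats::setNames(verts, verts),
                function(v) ch[which(ch[-n] == v) + 1L])
  last <- ch[n]
  for (try in 1:500) {
    lastEdge <- list()
    for (v in verts)
      if (v != last && length(adj[[v]]))
        lastEdge[[v]] <- sample(adj[[v]], 1L)
    # the chosen last edges must connect every vertex to the final one
    ok <- TRUE
    for (v in names(lastEdge)) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || is.null(lastEdge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lastEdge[[cur]]
      }
      if (!ok) break
    }
    if (!ok) next
    walk_adj <- list()
    for (v in verts) {
      edges <- adj[[v]]
      if (v %in% names(lastEdge)) {
        k <- match(lastEdge[[v]], edges)
        edges <- c(sample(edges[-k]), edges[k])
      } else edges <- sample(edges)
      walk_adj[[v]] <- edges
    }
    out <- character(n)
    out[1L] <- ch[1L]
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    for (i in 2:n) {
      v <- out[i - 1L]
      out[i] <- walk_adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
    }
    return(paste(out, collapse = ""))
  }
  stop("dinucleotideShuffle: failed to sample a valid Euler walk")
}

#' Shuffle internal CDS codons
#'
#' Random permutation of all codons between the start and stop codons,
#' preserving CDS length and the start/stop codons themselves.
#'
#' @param sequence transcript RNA sequence.
#' @param cds 0-based half-open CDS span including the stop codon.
#' @return sequence with permuted internal codons.
#' @export
codonShuffle <- function(sequence, cds) {
  ncod <- (cds[2L] - cds[1L]) / 3L
  if (ncod <= 3L) return(sequence)
  starts <- cds[1L] + 3L * (1:(ncod - 2L))        # internal codons, 0-based
  codons <- substring(sequence, starts + 1L, starts + 3L)
  perm <- sample(codons)
  paste0(substr(sequence, 1L, cds[1L] + 3L),
         paste(perm, collapse = ""),
         substr(sequence, cds[2L] - 2L, nchar(sequence)))
}

# all single-base substitutions creating an in-frame premature stop
.nonsenseVariants <- function(sequence, cds) {
  ch <- strsplit(sequence, "")[[1L]]
  ncod <- (cds[2L] - cds[1L]) / 3L
  out <- list()
  for (ci in 0:(ncod - 2L)) {                      # exclude the stop codon
    cs <- cds[1L] + 3L * ci
    cod <- ch[(cs + 1L):(cs + 3L)]
    if (paste(cod, collapse = "") %in% STOP_CODONS) next
    for (off in 1:3) {
      for (b in setdiff(RNA_BASES, cod[off])) {
        mut <- cod; mut[off] <- b
        if (paste(mut, collapse = "") %in% STOP_CODONS)
          out[[length(out) + 1L]] <- data.frame(
            position = cs + off - 1L, ref = cod[off], alt = b,
            codonIndex = ci, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(0), ref = character(0),
               alt = character(0), codonIndex = integer(0))
}

#' Score sequence perturbations against the wild type
#'
#' Generates the requested perturbation variants and scores each as
#' \eqn{\Delta S} relative to the wild type.  Perturbations:
#' \code{utr5_dinuc_shuffle} / \code{utr3_dinuc_shuffle} (UTRs longer
#' than 25 nt only, preserving dinucleotide counts),
#' \code{codon_shuffle} (internal CDS codons), \code{start_knockout}
#' (the 9 single-base substitutions in the start codon), and
#' \code{nonsense_scan} (all substitutions creating an in-frame premature
#' stop, annotated with fifty-codon bins along the CDS).
#'
#' @param model a \code{\link{SeqModel}} or scorer list.
#' @param sequence transcript RNA sequence.
#' @param cds 0-based half-open CDS (the longest ORF may be supplied for
#'   noncoding records); NULL makes CDS-dependent perturbations
#'   inapplicable.
#' @param perturbation perturbation name.
#' @param seed integer seed for the shuffles.
#' @param nShuffles shuffle replicates (shuffle perturbations only).
#' @return data.frame with a \code{deltaS} column plus per-perturbation
#'   metadata; zero rows with a \code{"reason"} attribute when
#'   inapplicable.
#' @export
perturbAndScore <- function(model, sequence, cds,
                            perturbation = c("utr5_dinuc_shuffle",
                                             "utr3_dinuc_shuffle",
                                             "codon_shuffle",
                                             "start_knockout",
                                             "nonsense_scan"),
                            seed = 1L, nShuffles = 1L) {
  perturbation <- match.arg(perturbation)
  sc <- .asScorer(model)
  set.seed(seed)
  empty <- function(reason) {
    out <- data.frame(deltaS = numeric(0))
    attr(out, "reason") <- reason
    out
  }
  if (is.null(cds) || anyNA(cds)) return(empty("no CDS/ORF span"))
  L <- nchar(sequence)
  S0 <- sc$score(seqToOneHot(sequence))
  scoreSeq <- function(s) sc$score(seqToOneHot(s)) - S0
  if (perturbation %in% c("utr5_dinuc_shuffle", "utr3_dinuc_shuffle")) {
    if (perturbation == "utr5_dinuc_shuffle") { a <- 0L; b <- cds[1L] }
    else { a <- cds[2L]; b <- L }
    if (b - a <= 25L) return(empty("UTR not longer than 25 nt"))
    ds <- vapply(seq_len(nShuffles), function(k) {
      utr <- dinucleotideShuffle(substr(sequence, a + 1L, b))
      s2 <- paste0(substr(sequence, 1L, a), utr,
                   substr(sequence, b + 1L, L))
      scoreSeq(s2)
    }, 0)
    return(data.frame(deltaS = ds, shuffle = seq_len(nShuffles)))
  }
  if (perturbation == "codon_shuffle") {
    ds <- vapply(seq_len(nShuffles), function(k)
      scoreSeq(codonShuffle(sequence, cds)), 0)
    return(data.frame(deltaS = ds, shuffle = seq_len(nShuffles)))
  }
  if (perturbation == "start_knockout") {
    rows <- list()
    ch <- strsplit(sequence, "")[[1L]]
    for (off in 1:3) {
      pos <- cds[1L] + off               # 1-based
      for (b in setdiff(RNA_BASES, ch[pos])) {
        s2 <- sequence
        substr(s2, pos, pos) <- b
        rows[[length(rows) + 1L]] <- data.frame(
          deltaS = scoreSeq(s2), position = pos - 1L, ref = ch[pos], alt = b)
      }
    }
    return(do.call(rbind, rows))
  }
  # nonsense_scan
  vars <- .nonsenseVariants(sequence, cds)
  if (!nrow(vars)) return(empty("no nonsense-creating substitutions"))
  vars$deltaS <- vapply(seq_len(nrow(vars)), function(r) {
    s2 <- sequence
    substr(s2, vars$position[r] + 1L, vars$position[r] + 1L) <- vars$alt[r]
    scoreSeq(s2)
  }, 0)
  vars$bin <- vars$codonIndex %/% 50L
  vars
}

#' Metagene of encoder-decoder attention at the first decoding step
#'
#' Extracts the chosen head's attention distribution over input
#' positions at the first decode step for every transcript, anchors at
#' the start codon (or longest-ORF start for noncoding records), and
#' averages into a metagene.
#'
#' @param model a \code{\link{SeqModel}}.
#' @param transcripts a \code{\link{TranscriptSet}}.
#' @param head,layer attention head and decoder layer (1-based).
#' @param coverageThreshold metagene coverage threshold.
#' @return a \code{\link{MetageneProfile}}.
#' @export
attentionSummary <- function(model, transcripts, head = 1L, layer = 1L,
                             coverageThreshold = 0.70) {
  ids <- transcriptIds(transcripts)
  series <- list(); anchors <- integer(0)
  for (id in ids) {
    s <- transcriptSeqs(transcripts)[[id]]
    cds <- cdsRanges(transcripts)[id, ]
    anchor <- if (!anyNA(cds)) cds[1L] else {
      o <- longestOrf(s)
      if (is.null(o)) next else o$start
    }
    H <- encode(model, s)
    st <- decodeStep(model, "<s>", H)
    A <- st$attention[[layer]]
    series[[length(series) + 1L]] <- A[1L, , head]
    anchors <- c(anchors, anchor)
  }
  metagene(series, anchors, coverageThreshold, anchor = "start_codon")
}
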