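#' Partition transcripts into train/validation/test splits
#'
#' The training portion is class-balanced and the per-class length
#' histograms (fixed bin width) are matched greedily: within each length
#' bin the two classes contribute equal numbers of training records, with
#' per-bin quotas scaled to reach the target training size.  Remaining
#' records are split between validation and test stratified by class.
#' Deterministic under \code{seed}.
#'
#' @param x a \code{TranscriptSet}.
#' @param fractions numeric length-3 vector summing to 1
#'   (train/validation/test; default \code{c(0.8, 0.1, 0.1)}).
#' @param seed integer seed.
#' @param binWidth length-histogram bin width in nucleotides.
#' @return a \code{\link{DatasetSplit}}.
#' @export
makeSplits <- function(x, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                       binWidth = 100L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  set.seed(seed)
  ids <- transcriptIds(x)
  lens <- Biostrings::width(x@seqs)
  lab <- x@label
  bins <- lens %/% binWidth
  n <- length(ids)
  t_per_class <- floor(round(fractions[1L] * n) / 2)

  train <- character(0)
  bin_levels <- sort(unique(bins))
  quota <- vapply(bin_levels, function(b)
    min(sum(lab == "PC" & bins == b), sum(lab == "NC" & bins == b)), 1L)
  total_q <- sum(quota)
  if (total_q < t_per_class) {
    warning("not enough length-matched pairs for a fully balanced training ",
            "split; taking best effort (", total_q, " pairs per class)")
    take <- quota
  } else {
    take <- floor(quota * t_per_class / total_q)
    # distribute the rounding remainder over bins with spare capacity
    rem <- t_per_class - sum(take)
    spare <- order(-(quota - take))
    k <- 1L
    while (rem > 0L && k <= length(spare)) {
      b <- spare[k]
      if (take[b] < quota[b]) { take[b] <- take[b] + 1L; rem <- rem - 1L }
      k <- if (k == length(spare)) 1L else k + 1L
      if (all(take >= quota)) break
    }
  }
  for (k in seq_along(bin_levels)) {
    if (take[k] == 0L) next
    for (cl in c("PC", "NC")) {
      pool <- ids[lab == cl & bins == bin_levels[k]]
      train <- c(train, sample(pool, take[k]))
    }
  }
  rest <- setdiff(ids, train)
  f_val <- fractions[2L] / (fractions[2L] + fractions[3L])
  val <- character(0)
  for (cl in c("PC", "NC")) {
    pool <- rest[lab[match(rest, ids)] == cl]
    val <- c(val, sample(pool, round(f_val * length(pool))))
  }
  test <- setdiff(rest, val)
  new("DatasetSplit", train = train, validation = val, test = test,
      seed = as.integer(seed))
}

#' Maximum per-bin class-count discrepancy of a length histogram
#'
#' Diagnostic for split balancing: the largest absolute difference, over
#' length bins, between PC and NC record counts among the given ids.
#'
#' @param x a \code{TranscriptSet}.
#' @param ids transcript ids to evaluate (e.g. a training split).
#' @param binWidth histogram bin width in nucleotides.
#' @return a single integer.
#' @export
binDiscrepancy <- function(x, ids, binWidth = 100L) {
  idx <- match(ids, transcriptIds(x))
  lens <- Biostrings::width(x@seqs)[idx]
  lab <- x@label[idx]
  bins <- lens %/% binWidth
  lv <- sort(unique(bins))
  max(vapply(lv, function(b)
    abs(sum(lab == "PC" & bins == b) - sum(lab == "NC" & bins == b)), 1L))
}
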