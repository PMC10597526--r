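#' @importFrom methods new validObject is setValidity show slot
#' @importClassesFrom Biostrings RNAStringSet
NULL

RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

#' TranscriptSet: a set of RNA transcripts with coding annotations
#'
#' The universal input container of the package.  Each record carries an
#' RNA sequence (DNA input is normalized to the RNA alphabet on read), a
#' class label (\code{"PC"} protein-coding or \code{"NC"} noncoding), and,
#' for coding records, a CDS span and the encoded protein.  Coordinates
#' are 0-based half-open throughout the package and the CDS span includes
#' the stop codon (RefSeq convention).
#'
#' Validity enforces: CDS length divisible by 3; \code{0 <= start < end <=
#' length}; the CDS begins with AUG unless the record is flagged
#' non-AUG-initiated; and translation of the CDS (minus the stop codon)
#' equals the stored protein.
#'
#' @slot seqs an \code{RNAStringSet}; names are transcript ids.
#' @slot label character vector, \code{"PC"} or \code{"NC"} per record.
#' @slot cds integer matrix with columns \code{start}, \code{end}
#'   (0-based half-open, stop codon included); \code{NA} rows for records
#'   without an annotated CDS.
#' @slot protein character vector of amino-acid strings (\code{NA} when
#'   absent).
#' @slot nonAUG logical; \code{TRUE} relaxes the AUG-start invariant for
#'   records with non-canonical initiation.
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  representation(
    seqs = "RNAStringSet",
    label = "character",
    cds = "matrix",
    protein = "character",
    nonAUG = "logical"
  )
)

setValidity("TranscriptSet", function(object) {
  n <- length(object@seqs)
  msgs <- character(0)
  if (length(object@label) != n || length(object@protein) != n ||
      length(object@nonAUG) != n || nrow(object@cds) != n) {
    return("slot lengths disagree with the number of sequences")
  }
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msgs <- c(msgs, "sequences must have unique names (transcript ids)")
  if (!all(object@label %in% c("PC", "NC")))
    msgs <- c(msgs, "labels must be 'PC' or 'NC'")
  lens <- Biostrings::width(object@seqs)
  ids <- names(object@seqs)
  for (i in seq_len(n)) {
    st <- object@cds[i, 1L]; en <- object@cds[i, 2L]
    if (is.na(st) != is.na(en)) {
      msgs <- c(msgs, sprintf("record %s: half-specified CDS", ids[i]))
      next
    }
    if (is.na(st)) next
    s <- as.character(object@seqs[[i]])
    if (st < 0L || st >= en || en > lens[i]) {
      msgs <- c(msgs, sprintf("record %s: CDS [%d,%d) out of bounds", ids[i], st, en))
      next
    }
    if ((en - st) %% 3L != 0L)
      msgs <- c(msgs, sprintf("record %s: CDS length not a multiple of 3", ids[i]))
    if (!object@nonAUG[i] && substr(s, st + 1L, st + 3L) != "AUG")
      msgs <- c(msgs, sprintf("record %s: CDS does not start with AUG", ids[i]))
    if (!is.na(object@protein[i]) && (en - st) >= 6L) {
      tr <- tryCatch(translateRNA(substr(s, st + 1L, en - 3L)), error = function(e) NA)
      if (!identical(tr, object@protein[i]))
        msgs <- c(msgs, sprintf("record %s: CDS translation does not match protein", ids[i]))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' DatasetSplit: train/validation/test partition of transcript ids
#'
#' @slot train,validation,test character vectors of transcript ids; the
#'   three sets are disjoint and together cover the input set.
#' @slot seed integer seed the split was drawn under.
#' @exportClass DatasetSplit
setClass("DatasetSplit",
  representation(train = "character", validation = "character",
                 test = "character", seed = "integer")
)

setValidity("DatasetSplit", function(object) {
  all_ids <- c(object@train, object@validation, object@test)
  if (anyDuplicated(all_ids)) "split partitions are not disjoint" else TRUE
})

#' MutationEffectMatrix: per-substitution coding-score changes
#'
#' An L x 3 matrix of \eqn{\Delta S} values, one per non-endogenous base
#' substitution per position.  \eqn{S} is the PC-vs-NC logit difference at
#' the first decoding position; \eqn{\Delta S} compares a single-nucleotide
#' variant with its wild type.  Columns are ordered alphabetically over the
#' three non-endogenous bases at each position; the wild-type sequence is
#' stored so rows can be interpreted.
#'
#' @slot values numeric L x 3 matrix of delta-S values.
#' @slot refSequence wild-type RNA sequence (character).
#' @slot method one of \code{"ism"}, \code{"taylor"}, \code{"ig_uniform"},
#'   \code{"mdig"}.
#' @slot beta,steps method hyperparameters (NA when not applicable).
#' @slot modelId identifier of the scoring model.
#' @exportClass MutationEffectMatrix
setClass("MutationEffectMatrix",
  representation(values = "matrix", refSequence = "character",
                 method = "character", beta = "numeric",
                 steps = "numeric", modelId = "character")
)

setValidity("MutationEffectMatrix", function(object) {
  if (ncol(object@values) != 3L) return("values must have 3 columns")
  if (nrow(object@values) != nchar(object@refSequence))
    return("row count must equal transcript length")
  if (!all(is.finite(object@values))) return("values must be finite")
  if (!object@method %in% c("ism", "taylor", "ig_uniform", "mdig", "other"))
    return("unknown method")
  TRUE
})

#' ImportanceTrack: per-position scalar importance under a direction
#'
#' Counterfactual-class importance: under \code{up_PC}, the importance of
#' position i is the strongest push toward NC achievable by mutating it
#' (max over b of \eqn{-\Delta S}, clipped at 0); \code{up_NC} is
#' symmetric with \eqn{+\Delta S}.  Masked positions are never selected as
#' maxima downstream.
#'
#' @slot values nonnegative numeric vector, one per position.
#' @slot direction \code{"up_PC"} or \code{"up_NC"}.
#' @slot mask logical vector flagging excluded positions.
#' @exportClass ImportanceTrack
setClass("ImportanceTrack",
  representation(values = "numeric", direction = "character", mask = "logical")
)

setValidity("ImportanceTrack", function(object) {
  if (length(object@mask) != length(object@values))
    return("mask and values lengths differ")
  if (!object@direction %in% c("up_PC", "up_NC")) return("bad direction")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("values must be finite and nonnegative")
  TRUE
})

#' MetageneProfile: an anchored average of per-position signals
#'
#' @slot position integer vector of relative positions (or bin indices).
#' @slot mean numeric mean signal per position/bin.
#' @slot coverage numeric fraction of contributing series per position.
#' @slot anchor description of the alignment anchor.
#' @exportClass MetageneProfile
setClass("MetageneProfile",
  representation(position = "integer", mean = "numeric",
                 coverage = "numeric", anchor = "character")
)

setValidity("MetageneProfile", function(object) {
  if (length(object@position) != length(object@mean) ||
      length(object@mean) != length(object@coverage))
    return("slot lengths differ")
  TRUE
})

#' SeqModel: an encoder-decoder coding-potential model
#'
#' Thin S4 wrapper holding the model configuration and the flat list of
#' parameter arrays.  Construct with \code{\link{buildModel}}.
#'
#' @slot config list of architecture settings (see \code{\link{modelConfig}}).
#' @slot params named list of numeric parameter arrays.
#' @exportClass SeqModel
setClass("SeqModel", representation(config = "list", params = "list"))

setMethod("show", "TranscriptSet", function(object) {
  n <- length(object@seqs)
  npc <- sum(object@label == "PC")
  cat(sprintf("TranscriptSet with %d transcripts (%d PC, %d NC)\n",
              n, npc, n - npc))
  if (n > 0) {
    lens <- Biostrings::width(object@seqs)
    cat(sprintf("  length range: %d-%d nt\n", min(lens), max(lens)))
  }
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d validation / %d test (seed %d)\n",
              length(object@train), length(object@validation),
              length(object@test), object@seed))
})

setMethod("show", "MutationEffectMatrix", function(object) {
  cat(sprintf("MutationEffectMatrix (%s): %d positions x 3 substitutions\n",
              object@method, nrow(object@values)))
})

setMethod("show", "SeqModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("SeqModel: %s encoder, task '%s', %d parameters\n",
              object@config$encoder, object@config$task, np))
})
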