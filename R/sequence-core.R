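#' Translate an RNA sequence with the standard genetic code
#'
#' Translation starts at \code{offset} (0-based) and proceeds codon by
#' codon until the first stop codon or until fewer than 3 nucleotides
#' remain.  The stop codon is not represented in the output.
#'
#' @param sequence character RNA sequence over \code{A,C,G,U}.
#' @param offset 0-based frame offset (default 0).
#' @return amino-acid string (possibly empty).
#' @examples
#' translateRNA("AUGAAAUAA")   # "MK"
#' @export
translateRNA <- function(sequence, offset = 0L) {
  stopifnot(length(sequence) == 1L, offset >= 0L)
  if (nchar(sequence) - offset < 3L)
    stop("sequence too short to translate from offset ", offset)
  if (grepl("[^ACGU]", sequence))
    stop("translateRNA: sequence contains non-ACGU characters")
  starts <- seq.int(offset + 1L, nchar(sequence) - 2L, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  aas <- Biostrings::RNA_GENETIC_CODE[codons]
  stop_at <- which(aas == "*")
  if (length(stop_at)) aas <- aas[seq_len(stop_at[1L] - 1L)]
  paste(aas, collapse = "")
}

#' Find all sense open reading frames
#'
#' Enumerates every AUG-initiated, in-frame-stop-terminated ORF in the
#' three sense frames.  Nested ORFs sharing a stop are all reported.
#' Coordinates are 0-based half-open and include the stop codon.
#'
#' @param sequence character RNA sequence.
#' @return data.frame with columns \code{start}, \code{end}, \code{frame},
#'   \code{protein}; zero rows when no ORF exists.
#' @export
findOrfs <- function(sequence) {
  L <- nchar(sequence)
  out <- list()
  if (L >= 6L && !grepl("[^ACGU]", sequence)) {
    for (frame in 0:2) {
      if (L - frame < 6L) next
      starts <- seq.int(frame + 1L, L - 2L, by = 3L)
      codons <- substring(sequence, starts, starts + 2L)
      aug <- which(codons == "AUG")
      stp <- which(codons %in% STOP_CODONS)
      if (!length(aug) || !length(stp)) next
      for (a in aug) {
        nxt <- stp[stp > a]
        if (!length(nxt)) next
        s0 <- starts[a] - 1L           # 0-based start
        e0 <- starts[nxt[1L]] + 2L     # 0-based half-open end incl. stop
        prot <- paste(Biostrings::RNA_GENETIC_CODE[codons[a:(nxt[1L] - 1L)]],
                      collapse = "")
        out[[length(out) + 1L]] <-
          data.frame(start = s0, end = e0, frame = frame, protein = prot,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Longest open reading frame
#'
#' Maximal ORF by nucleotide length; ties broken by 5'-most start, then by
#' lowest frame index.
#'
#' @param sequence character RNA sequence.
#' @return one-row data.frame as in \code{\link{findOrfs}}, or \code{NULL}
#'   when no ORF exists.
#' @export
longestOrf <- function(sequence) {
  orfs <- findOrfs(sequence)
  if (!nrow(orfs)) return(NULL)
  len <- orfs$end - orfs$start
  ord <- order(-len, orfs$start, orfs$frame)
  orfs[ord[1L], , drop = FALSE]
}

.normalizeRNA <- function(x) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop("sequence(s) with characters outside ACGU/ACGT: ",
         paste(utils::head(which(bad), 3), collapse = ", "))
  x
}

#' Construct a TranscriptSet
#'
#' @param ids character ids (unique).
#' @param sequences character RNA/DNA sequences (T normalized to U).
#' @param label character, \code{"PC"} or \code{"NC"}.
#' @param cdsStart,cdsEnd 0-based half-open CDS bounds including the stop
#'   codon; \code{NA} when absent.
#' @param protein amino-acid strings (\code{NA} when absent).
#' @param nonAUG logical flag relaxing the AUG-start invariant.
#' @return a validated \code{\link{TranscriptSet}}.
#' @export
transcriptSet <- function(ids, sequences, label,
                          cdsStart = NA_integer_, cdsEnd = NA_integer_,
                          protein = NA_character_, nonAUG = FALSE) {
  n <- length(ids)
  seqs <- Biostrings::RNAStringSet(.normalizeRNA(sequences))
  names(seqs) <- ids
  cds <- cbind(start = as.integer(rep_len(cdsStart, n)),
               end = as.integer(rep_len(cdsEnd, n)))
  new("TranscriptSet", seqs = seqs, label = rep_len(label, n), cds = cds,
      protein = rep_len(as.character(protein), n),
      nonAUG = rep_len(nonAUG, n))
}

#' @describeIn transcriptSet number of transcripts
#' @param x,i a TranscriptSet and an index
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@seqs))

#' @describeIn transcriptSet subset records
#' @export
setMethod("[", "TranscriptSet", function(x, i) {
  new("TranscriptSet", seqs = x@seqs[i], label = x@label[i],
      cds = x@cds[i, , drop = FALSE], protein = x@protein[i],
      nonAUG = x@nonAUG[i])
})

#' Accessors for TranscriptSet
#'
#' \code{transcriptIds} returns record ids, \code{transcriptSeqs} the
#' sequences as a character vector, \code{transcriptLabels} the PC/NC
#' labels, \code{cdsRanges} the 0-based half-open CDS matrix,
#' \code{transcriptProteins} the annotated proteins.
#'
#' @param x a \code{TranscriptSet}.
#' @name transcript-accessors
NULL

#' @rdname transcript-accessors
#' @export
transcriptIds <- function(x) names(x@seqs)

#' @rdname transcript-accessors
#' @export
transcriptSeqs <- function(x) {
  s <- as.character(x@seqs)
  names(s) <- names(x@seqs)
  s
}

#' @rdname transcript-accessors
#' @export
transcriptLabels <- function(x) stats::setNames(x@label, names(x@seqs))

#' @rdname transcript-accessors
#' @export
cdsRanges <- function(x) {
  rownames(x@cds) <- names(x@seqs)
  x@cds
}

#' @rdname transcript-accessors
#' @export
transcriptProteins <- function(x) stats::setNames(x@protein, names(x@seqs))

#' Read transcripts from FASTA plus a tab-separated annotation table
#'
#' The annotation is a TSV with columns \code{id}, \code{label},
#' \code{cds_start}, \code{cds_end}, \code{protein} and optionally
#' \code{non_aug}.  Every FASTA record must have an annotation row; a
#' coding record without CDS/protein annotation is a hard error, as is a
#' CDS/protein mismatch (reported with the record id by validity).
#'
#' @param fastaPath path to a FASTA file (RNA or DNA alphabet).
#' @param annotationPath path to the TSV annotation.
#' @return a \code{\link{TranscriptSet}}.
#' @export
readTranscripts <- function(fastaPath, annotationPath) {
  raw <- Biostrings::readBStringSet(fastaPath)
  if (length(raw) == 0L)
    return(transcriptSet(character(0), character(0), character(0)))
  ids <- sub("\\s.*$", "", names(raw))
  ann <- utils::read.delim(annotationPath, stringsAsFactors = FALSE)
  need <- c("id", "label", "cds_start", "cds_end", "protein")
  if (!all(need %in% colnames(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(ids, ann$id)
  if (length(miss))
    stop("missing annotation for record(s): ", paste(miss, collapse = ", "))
  ann <- ann[match(ids, ann$id), ]
  pc_noann <- ann$label == "PC" & (is.na(ann$cds_start) | is.na(ann$protein))
  if (any(pc_noann))
    stop("coding record(s) without CDS/protein annotation: ",
         paste(ann$id[pc_noann], collapse = ", "))
  nonAUG <- if ("non_aug" %in% colnames(ann)) as.logical(ann$non_aug) else FALSE
  transcriptSet(ids, as.character(raw), ann$label,
                cdsStart = ann$cds_start, cdsEnd = ann$cds_end,
                protein = ann$protein, nonAUG = nonAUG)
}

#' Write transcripts to FASTA plus annotation TSV
#'
#' Inverse of \code{\link{readTranscripts}}; a read/write round trip is
#' the identity.
#'
#' @param x a \code{TranscriptSet}.
#' @param fastaPath,annotationPath output paths.
#' @export
writeTranscripts <- function(x, fastaPath, annotationPath) {
  Biostrings::writeXStringSet(x@seqs, fastaPath)
  ann <- data.frame(id = names(x@seqs), label = x@label,
                    cds_start = x@cds[, 1L], cds_end = x@cds[, 2L],
                    protein = x@protein, non_aug = x@nonAUG,
                    stringsAsFactors = FALSE)
  utils::write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Drop transcripts above a length cutoff
#'
#' @param x a \code{TranscriptSet}.
#' @param maxLength maximum retained length in nucleotides (default 1200).
#' @export
filterByLength <- function(x, maxLength = 1200L) {
  keep <- Biostrings::width(x@seqs) <= maxLength
  x[keep]
}
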