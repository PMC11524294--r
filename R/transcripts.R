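#' Construct a transcript set
#'
#' A transcript set is the coordinate frame for every editing site: each
#' transcript carries its sequence and a contiguous 5'UTR / CDS / 3'UTR
#' partition in 0-based half-open coordinates.  Empty UTRs are the empty
#' intervals \code{[0,0)} and \code{[len,len)}.
#'
#' @param id character vector of transcript identifiers (unique).
#' @param sequence character vector of nucleotide strings (A/C/G/T/N).
#' @param cds_start,cds_end 0-based half-open CDS bounds; the 5'UTR is
#'   \code{[0, cds_start)} and the 3'UTR \code{[cds_end, len)}.
#' @return a \code{transcript_set}: a data.frame with columns \code{id},
#'   \code{sequence}, \code{length}, \code{utr5_start}, \code{utr5_end},
#'   \code{cds_start}, \code{cds_end}, \code{utr3_start}, \code{utr3_end}.
#' @export
transcript_set <- function(id, sequence, cds_start, cds_end) {
  len <- nchar(sequence)
  tx <- data.frame(
    id = as.character(id), sequence = as.character(sequence),
    length = as.integer(len),
    utr5_start = 0L, utr5_end = as.integer(cds_start),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    utr3_start = as.integer(cds_end), utr3_end = as.integer(len),
    stringsAsFactors = FALSE
  )
  class(tx) <- c("transcript_set", "data.frame")
  validate_transcripts(tx)
  tx
}

#' Validate transcript-set invariants
#'
#' Checks that regions are ordered, disjoint and cover the full length,
#' that CDS lengths are divisible by 3 and that ids are unique.  Stops with
#' a message naming the offending transcript.
#'
#' @param tx a \code{transcript_set}.
#' @return \code{tx}, invisibly.
#' @export
validate_transcripts <- function(tx) {
  stopifnot(is.data.frame(tx), nrow(tx) >= 1)
  if (anyDuplicated(tx$id))
    stop("duplicate transcript ids: ",
         paste(unique(tx$id[duplicated(tx$id)]), collapse = ", "))
  bad <- function(cond, what) {
    if (any(cond))
      stop("transcript ", tx$id[which(cond)[1]], ": ", what)
  }
  bad(tx$length < 1, "empty sequence")
  bad(nchar(tx$sequence) != tx$length, "length field disagrees with sequence")
  bad(tx$utr5_start != 0 | tx$utr5_end != tx$cds_start |
        tx$utr3_start != tx$cds_end | tx$utr3_end != tx$length,
      "regions do not partition the transcript")
  bad(tx$cds_start < 0 | tx$cds_end < tx$cds_start | tx$cds_end > tx$length,
      "CDS interval out of bounds or reversed")
  bad((tx$cds_end - tx$cds_start) %% 3 != 0, "CDS length not divisible by 3")
  invisible(tx)
}

tx_row <- function(tx, id) {
  i <- match(id, tx$id)
  if (is.na(i)) stop("unknown transcript: ", id)
  tx[i, , drop = FALSE]
}

# vectorized base lookup, 0-based positions
tx_base <- function(tx, transcript_id, position) {
  i <- match(transcript_id, tx$id)
  if (anyNA(i)) stop("unknown transcript: ",
                     transcript_id[which(is.na(i))[1]])
  substring(tx$sequence[i], position + 1L, position + 1L)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x), "transcripts,",
      sum(x$length), "nt total;",
      sum(x$cds_end - x$cds_start), "nt CDS\n")
  invisible(x)
}
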