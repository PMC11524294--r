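STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all64 <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  setdiff(all64, STOP_CODONS)
}

#' Generate a synthetic transcript set
#'
#' Each transcript is a contiguous 5'UTR + CDS + 3'UTR.  UTRs are uniform
#' random sequence; the CDS starts with ATG, ends with a stop codon and
#' contains no internal in-frame stop.  Lengths are drawn uniformly from
#' the configured ranges (CDS lengths as multiples of 3).
#'
#' @param config a [sim_config()].
#' @return a [transcript_set()].
#' @export
generate_transcripts <- function(config) {
  validate_sim_config(config)
  with_op_seed(config$seed, SIM_OFFSETS["transcripts"], {
    n <- config$n_transcripts
    rlen <- function(r) if (r[1] == r[2]) rep(r[1], n) else
      sample(seq(r[1], r[2]), n, replace = TRUE)
    u5 <- rlen(config$utr5_len)
    u3 <- rlen(config$utr3_len)
    ncodon <- {
      r <- pmax(2L, config$cds_len %/% 3L)
      if (r[1] == r[2]) rep(r[1], n) else sample(seq(r[1], r[2]), n, TRUE)
    }
    sense <- sense_codons()
    rand_seq <- function(k) if (k == 0) "" else
      paste(sample(BASES, k, replace = TRUE), collapse = "")
    seqs <- character(n)
    for (i in seq_len(n)) {
      body <- if (ncodon[i] > 2)
        paste(sample(sense, ncodon[i] - 2L, replace = TRUE), collapse = "")
      else ""
      cds <- paste0("ATG", body, sample(STOP_CODONS, 1))
      seqs[i] <- paste0(rand_seq(u5[i]), cds, rand_seq(u3[i]))
    }
    transcript_set(
      id = sprintf("tx%04d", seq_len(n)), sequence = seqs,
      cds_start = u5, cds_end = u5 + 3L * ncodon
    )
  })
}

#' Plant editing events on a transcript set
#'
#' Draws \code{n_sites} events at distinct (transcript, position) pairs.
#' The substitution type of each event is sampled from the configured
#' weights; the position is then drawn uniformly among unused positions
#' whose reference base matches the type.  Positions within 5 bases of a
#' transcript end are never used, so every site has a full +/-5 flank.
#' True degrees are uniform over \code{degree_range}.
#'
#' @param transcripts a [transcript_set()].
#' @param config a [sim_config()].
#' @return data.frame of planted sites: \code{transcript_id},
#'   \code{position} (0-based), \code{ref_base}, \code{alt_base},
#'   \code{true_degree}.
#' @export
plant_sites <- function(transcripts, config) {
  validate_sim_config(config)
  empty <- data.frame(transcript_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      true_degree = numeric())
  if (config$n_sites == 0) return(empty)
  with_op_seed(config$seed, SIM_OFFSETS["sites"], {
    pool <- do.call(rbind, lapply(seq_len(nrow(transcripts)), function(i) {
      len <- transcripts$length[i]
      if (len < 11L) return(NULL)
      pos <- 5L:(len - 6L)
      data.frame(transcript_id = transcripts$id[i], position = pos,
                 ref = substring(transcripts$sequence[i], pos + 1L, pos + 1L),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pool) || config$n_sites > nrow(pool))
      stop("n_sites exceeds the number of plantable positions")
    w <- config$editing_types / sum(config$editing_types)
    avail <- split(seq_len(nrow(pool)), pool$ref)
    out <- vector("list", config$n_sites)
    for (s in seq_len(config$n_sites)) {
      ws <- w
      repeat {
        if (sum(ws) <= 0) stop("no plantable positions left for any ",
                               "editing type with positive weight")
        type <- sample(names(ws), 1, prob = ws)
        ref <- substr(type, 1, 1)
        if (length(avail[[ref]]) > 0) break
        ws[substr(names(ws), 1, 1) == ref] <- 0
      }
      j <- if (length(avail[[ref]]) == 1) avail[[ref]] else
        sample(avail[[ref]], 1)
      avail[[ref]] <- setdiff(avail[[ref]], j)
      out[[s]] <- data.frame(
        transcript_id = pool$transcript_id[j], position = pool$position[j],
        ref_base = ref, alt_base = substr(type, 3, 3),
        stringsAsFactors = FALSE
      )
    }
    sites <- do.call(rbind, out)
    dr <- config$degree_range
    sites$true_degree <- if (dr[1] == dr[2]) rep(dr[1], nrow(sites)) else
      runif(nrow(sites), dr[1], dr[2])
    sites[order(sites$transcript_id, sites$position), , drop = FALSE]
  })
}

# in-frame internal stop check for a CDS nucleotide string (terminal codon
# is allowed to be a stop)
has_internal_stop <- function(cds_seq) {
  k <- nchar(cds_seq) %/% 3L
  if (k <= 1L) return(FALSE)
  starts <- 3L * (seq_len(k - 1L) - 1L) + 1L
  any(substring(cds_seq, starts, starts + 2L) %in% STOP_CODONS)
}

#' Rewrite the -1/+1 flanks of planted C-to-U sites toward purines
#'
#' With probability \code{motif_prob} per site, the bases immediately
#' up- and downstream of a planted C-to-U site are set to A or G (equal
#' odds), emulating a purine-biased cis-element around edited C residues.
#' Rewrites inside a CDS that would create an internal in-frame stop are
#' resampled among the four purine pairs; if every pair creates a stop the
#' site is left untouched.  Positions occupied by another planted site are
#' never rewritten (the pileup ground truth must stay valid).
#'
#' @param transcripts a [transcript_set()].
#' @param planted planted-site table from [plant_sites()].
#' @param config a [sim_config()].
#' @return list with elements \code{transcripts} (rewritten set),
#'   \code{n_rewritten} and \code{n_skipped}.
#' @export
embed_motif_context <- function(transcripts, planted, config) {
  validate_sim_config(config)
  tx <- transcripts
  ctu <- planted[planted$ref_base == "C" & planted$alt_base == "T", ,
                 drop = FALSE]
  n_rewritten <- 0L; n_skipped <- 0L
  occupied <- paste(planted$transcript_id, planted$position)
  with_op_seed(config$seed, SIM_OFFSETS["motif"], {
    for (s in seq_len(nrow(ctu))) {
      i <- match(ctu$transcript_id[s], tx$id)
      pos <- ctu$position[s]
      if (pos < 5L || pos > tx$length[i] - 6L) { n_skipped <- n_skipped + 1L; next }
      if (runif(1) >= config$motif_prob) next
      if (any(paste(tx$id[i], c(pos - 1L, pos + 1L)) %in% occupied)) {
        n_skipped <- n_skipped + 1L; next
      }
      pairs <- expand.grid(up = PURINES, dn = PURINES,
                           stringsAsFactors = FALSE)
      pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
      seq0 <- tx$sequence[i]
      done <- FALSE
      for (p in seq_len(nrow(pairs))) {
        cand <- seq0
        substr(cand, pos, pos) <- pairs$up[p]          # pos-1, 1-based
        substr(cand, pos + 2L, pos + 2L) <- pairs$dn[p] # pos+1, 1-based
        cds <- substr(cand, tx$cds_start[i] + 1L, tx$cds_end[i])
        if (!has_internal_stop(cds)) {
          tx$sequence[i] <- cand
          done <- TRUE
          break
        }
      }
      if (done) n_rewritten <- n_rewritten + 1L else n_skipped <- n_skipped + 1L
    }
    list(transcripts = validate_transcripts(tx),
         n_rewritten = n_rewritten, n_skipped = n_skipped)
  })
}
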