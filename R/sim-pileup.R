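#' Simulate a base-count pileup over a transcript set
#'
#' Produces one column per transcript position.  Coverage is Poisson with
#' mean \code{coverage_mean}, truncated at >= 1.  At a planted site the
#' counts are multinomial with the alt base at probability
#' \code{true_degree + error_rate/3} and each other non-reference base at
#' \code{error_rate/3}; elsewhere each non-reference base has probability
#' \code{error_rate/3}.  Counts always sum to coverage.  The column mean
#' base quality encodes the error rate on the Phred scale
#' (\code{-10*log10(error_rate)}, capped at 93), so a caller reading the
#' quality recovers the simulation's error model.
#'
#' @param transcripts a [transcript_set()].
#' @param planted planted-site table from [plant_sites()] (may have 0 rows).
#' @param config a [sim_config()].
#' @return data.frame with columns \code{transcript_id}, \code{position}
#'   (0-based), \code{ref}, \code{coverage}, \code{A}, \code{C}, \code{G},
#'   \code{T}, \code{mean_qual}.
#' @export
simulate_pileup <- function(transcripts, planted, config) {
  validate_sim_config(config)
  with_op_seed(config$seed, SIM_OFFSETS["pileup"], {
    tx_id <- rep(transcripts$id, transcripts$length)
    pos <- unlist(lapply(transcripts$length, function(l) seq_len(l) - 1L),
                  use.names = FALSE)
    ref <- unlist(strsplit(transcripts$sequence, ""), use.names = FALSE)
    n <- length(ref)
    lambda <- config$coverage_mean
    # Poisson truncated at >= 1 by inverse-cdf above the zero mass
    cov <- qpois(runif(n, ppois(0, lambda), 1), lambda)

    e3 <- config$error_rate / 3
    prob <- matrix(e3, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
    ref_idx <- match(ref, BASES)
    prob[cbind(seq_len(n), ref_idx)] <- 0  # reference gets the remainder

    if (nrow(planted) > 0) {
      key <- paste(tx_id, pos)
      pkey <- paste(planted$transcript_id, planted$position)
      hit <- match(pkey, key)
      if (anyNA(hit)) stop("planted site outside the transcript set")
      prob[cbind(hit, match(planted$alt_base, BASES))] <-
        e3 + planted$true_degree
    }

    # exact multinomial by sequential conditional binomials over the three
    # non-reference bases (vectorized; the reference takes the remainder)
    counts <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
    remaining <- cov
    used_p <- rep(0, n)
    for (b in seq_len(4)) {
      pb <- prob[, b]
      sel <- pb > 0 & remaining > 0
      if (any(sel)) {
        cond_p <- pmin(1, pb[sel] / (1 - used_p[sel]))
        counts[sel, b] <- rbinom(sum(sel), remaining[sel], cond_p)
        remaining[sel] <- remaining[sel] - counts[sel, b]
      }
      used_p <- used_p + pb
    }
    counts[cbind(seq_len(n), ref_idx)] <-
      counts[cbind(seq_len(n), ref_idx)] + remaining

    qual <- if (config$error_rate > 0)
      min(93, -10 * log10(config$error_rate)) else 93
    data.frame(
      transcript_id = tx_id, position = pos, ref = ref,
      coverage = as.integer(cov),
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
      T = counts[, "T"],
      mean_qual = round(qual, 2),
      stringsAsFactors = FALSE
    )
  })
}
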