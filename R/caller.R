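#' Read-filter and calling policy
#'
#' The calling policy bundles the stringency thresholds of the pipeline:
#' perfect matches required over the first 22 aligned bases (the seed), at
#' most 3 mismatches per accepted read, a Phred-20 "high quality" floor, a
#' 50-read coverage floor for candidate sites, and an FDR level of 0.05.
#'
#' @param seed_length aligned bases that must match perfectly.
#' @param max_edits_per_read maximum mismatches in an accepted read.
#' @param min_base_quality Phred floor for a column to count as high
#'   quality.
#' @param min_coverage minimum high-quality reads at a candidate column.
#' @param alpha FDR level; sites are kept at adjusted p strictly below it.
#' @return list of class \code{read_filter_policy}.
#' @export
read_filter_policy <- function(seed_length = 22L, max_edits_per_read = 3L,
                               min_base_quality = 20, min_coverage = 50L,
                               alpha = 0.05) {
  stopifnot(seed_length > 0, max_edits_per_read >= 0,
            min_base_quality >= 0, min_coverage > 0,
            alpha > 0, alpha < 1)
  structure(list(seed_length = as.integer(seed_length),
                 max_edits_per_read = as.integer(max_edits_per_read),
                 min_base_quality = min_base_quality,
                 min_coverage = as.integer(min_coverage),
                 alpha = alpha),
            class = "read_filter_policy")
}

#' Accept or reject an aligned read
#'
#' A read is rejected when it is shorter than the seed, when any mismatch
#' falls within the first \code{seed_length} aligned bases, or when it
#' carries more than \code{max_edits_per_read} mismatches in total.
#'
#' @param read list with \code{length} (aligned bases) and
#'   \code{mismatch_positions} (0-based offsets of mismatches).
#' @param policy a [read_filter_policy()].
#' @return list with \code{accept} (logical) and \code{reason} ("ok",
#'   "short", "seed_mismatch" or "too_many_edits").
#' @export
filter_read <- function(read, policy = read_filter_policy()) {
  mm <- read$mismatch_positions %||% integer(0)
  if (read$length < policy$seed_length)
    return(list(accept = FALSE, reason = "short"))
  if (any(mm < policy$seed_length))
    return(list(accept = FALSE, reason = "seed_mismatch"))
  if (length(mm) > policy$max_edits_per_read)
    return(list(accept = FALSE, reason = "too_many_edits"))
  list(accept = TRUE, reason = "ok")
}

#' Enumerate candidate single-nucleotide variants from a pileup
#'
#' One candidate per (column, non-reference base with count >= 1).
#' Columns with coverage below \code{min_coverage} or mean quality below
#' \code{min_base_quality} are dropped.  The per-base error rate attached
#' to each candidate is \code{10^(-mean_qual/10)} unless a global
#' \code{error_rate} overrides it.
#'
#' Note: the read-level filters ([filter_read()]) apply upstream of pileup
#' construction; a pileup is assumed to contain already-filtered reads.
#'
#' @param pileup pileup data.frame (see [read_pileup()]).
#' @param policy a [read_filter_policy()].
#' @param error_rate optional global per-base error rate replacing the
#'   quality-derived one.
#' @return data.frame of candidates: \code{transcript_id},
#'   \code{position}, \code{ref}, \code{alt}, \code{coverage},
#'   \code{alt_count}, \code{error_rate}.
#' @export
collect_candidates <- function(pileup, policy = read_filter_policy(),
                               error_rate = NULL) {
  keep <- pileup$coverage >= policy$min_coverage &
    pileup$mean_qual >= policy$min_base_quality
  pu <- pileup[keep, , drop = FALSE]
  if (nrow(pu) == 0)
    return(data.frame(transcript_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      coverage = integer(), alt_count = integer(),
                      error_rate = numeric()))
  out <- vector("list", 4)
  for (b in BASES) {
    alt_n <- pu[[b]]
    sel <- pu$ref != b & alt_n >= 1L
    if (!any(sel)) next
    err <- if (is.null(error_rate)) 10^(-pu$mean_qual[sel] / 10) else
      rep(error_rate, sum(sel))
    out[[b]] <- data.frame(
      transcript_id = pu$transcript_id[sel], position = pu$position[sel],
      ref = pu$ref[sel], alt = b, coverage = pu$coverage[sel],
      alt_count = alt_n[sel], error_rate = err, stringsAsFactors = FALSE
    )
  }
  cand <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(cand)) cand <- data.frame(transcript_id = character(),
                                        position = integer(),
                                        ref = character(), alt = character(),
                                        coverage = integer(),
                                        alt_count = integer(),
                                        error_rate = numeric())
  rownames(cand) <- NULL
  cand[order(cand$transcript_id, cand$position, cand$alt), , drop = FALSE]
}

#' One-sided Fisher's exact test against the sequencing-error expectation
#'
#' Tests whether the observed alternative-base count exceeds what
#' sequencing error alone would produce.  The 2x2 table contrasts the
#' observed column, \code{(alt_count, coverage - alt_count)}, with the
#' expected-under-error column \code{(round(coverage * error_rate / 3),
#' rest)}; error is split over the three non-reference bases.  The
#' one-sided (greater) p-value is the hypergeometric tail, computed with
#' \code{phyper}.  Rounding of the expected count is round-half-to-even
#' (R's \code{round}), for bit-exact reproducibility.
#'
#' @param alt_count,coverage observed alternative reads and total reads
#'   (vectorized).
#' @param error_rate per-base error probability in (0,1) (vectorized).
#' @return p-values in (0,1].
#' @export
fisher_error_test <- function(alt_count, coverage, error_rate) {
  stopifnot(all(coverage >= 1), all(alt_count >= 0),
            all(error_rate > 0), all(error_rate < 1))
  if (any(alt_count > coverage))
    stop("alt_count exceeds coverage")
  expected <- round(coverage * error_rate / 3)
  # table [[a, n-a], [e, n-e]]; margins: rows (n, n), first column a+e.
  # One-sided greater tail: P(X >= a), X ~ Hypergeom drawing n of the
  # (a+e) "alt" items from 2n.
  phyper(alt_count - 1L, m = alt_count + expected,
         n = 2L * coverage - alt_count - expected,
         k = coverage, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (cumulative minimum over p * m / rank),
#' delegated to \code{stats::p.adjust}.
#'
#' @param p_values numeric vector in [0,1].
#' @return q-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Call editing sites from candidates
#'
#' Attaches Fisher p-values and BH q-values to each candidate and keeps
#' those with q strictly below \code{policy$alpha}.  Surviving sites get
#' the "X-to-Y" type label (U for T on the RNA side) and the editing
#' degree \code{alt_count / coverage}.
#'
#' @param candidates output of [collect_candidates()].
#' @param policy a [read_filter_policy()].
#' @return data.frame of editing sites (possibly 0 rows).
#' @export
call_sites <- function(candidates, policy = read_filter_policy()) {
  cand <- candidates
  cand$p_value <- if (nrow(cand) == 0) numeric(0) else
    fisher_error_test(cand$alt_count, cand$coverage, cand$error_rate)
  cand$q_value <- adjust_fdr(cand$p_value)
  sites <- cand[!is.na(cand$q_value) & cand$q_value < policy$alpha, ,
                drop = FALSE]
  sites$type_label <- if (nrow(sites)) edit_type_label(sites$ref, sites$alt)
  else character(0)
  sites$degree <- sites$alt_count / sites$coverage
  rownames(sites) <- NULL
  sites
}

#' End-to-end caller: pileup in, classed call set out
#'
#' Convenience wrapper running [collect_candidates()] and [call_sites()]
#' and recording the filter cascade (columns in, columns surviving the
#' coverage/quality cut, candidates, called sites).
#'
#' @param pileup pileup data.frame.
#' @param policy a [read_filter_policy()].
#' @param error_rate optional global error rate (see
#'   [collect_candidates()]).
#' @return object of class \code{editing_calls}: the site data.frame with
#'   attributes \code{policy} and \code{cascade}.
#' @export
call_editing_sites <- function(pileup, policy = read_filter_policy(),
                               error_rate = NULL) {
  cand <- collect_candidates(pileup, policy, error_rate)
  sites <- call_sites(cand, policy)
  attr(sites, "policy") <- policy
  attr(sites, "cascade") <- c(
    columns = nrow(pileup),
    high_quality_columns = sum(pileup$coverage >= policy$min_coverage &
                                 pileup$mean_qual >= policy$min_base_quality),
    candidates = nrow(cand),
    called = nrow(sites)
  )
  class(sites) <- c("editing_calls", "data.frame")
  sites
}

#' @export
print.editing_calls <- function(x, ...) {
  cas <- attr(x, "cascade")
  cat("editing_calls:", nrow(x), "sites\n")
  cat(sprintf("  cascade: %d columns -> %d high-quality -> %d candidates -> %d called\n",
              cas["columns"], cas["high_quality_columns"],
              cas["candidates"], cas["called"]))
  if (nrow(x) > 0) {
    cat("  types:\n")
    print(sort(table(x$type_label), decreasing = TRUE))
  }
  invisible(x)
}

#' @export
summary.editing_calls <- function(object, ...) {
  list(n_sites = nrow(object),
       cascade = attr(object, "cascade"),
       types = if (nrow(object)) table(object$type_label) else table(character(0)),
       mean_degree = if (nrow(object)) mean(object$degree) else NA_real_,
       alpha = attr(object, "policy")$alpha)
}
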