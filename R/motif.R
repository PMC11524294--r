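# Positional composition analysis of the +/-5 flanks of edited C residues:
# per-cluster composition matrices, a transcriptome background over all C
# residues, chi-square per position, and the IUPAC core-motif call.

MOTIF_POSITIONS <- -5:5

#' Extract the +/-5 flank around each C-to-U site
#'
#' Returns the 11-mer centered on the edited C.  Sites within 5 bases of a
#' transcript end are skipped (counted in the \code{"skipped"} attribute).
#' A site whose center base is not C is an error.
#'
#' @param sites C-to-U site table (\code{transcript_id}, \code{position}).
#' @param transcripts a [transcript_set()].
#' @param window half-window (fixed analysis uses 5).
#' @return character vector of 11-mers, attribute \code{skipped}.
#' @export
extract_flanks <- function(sites, transcripts, window = 5L) {
  if (nrow(sites) == 0)
    return(structure(character(0), skipped = 0L))
  i <- match(sites$transcript_id, transcripts$id)
  if (anyNA(i)) stop("unknown transcript in sites")
  ok <- sites$position >= window &
    sites$position <= transcripts$length[i] - window - 1L
  center <- tx_base(transcripts, sites$transcript_id[ok],
                    sites$position[ok])
  if (any(center != "C"))
    stop("flank extraction on a non-C center base")
  flanks <- substring(transcripts$sequence[i[ok]],
                      sites$position[ok] - window + 1L,
                      sites$position[ok] + window + 1L)
  structure(flanks, skipped = sum(!ok))
}

#' Base x position composition matrix of a set of flanks
#'
#' counts[b, p] = occurrences of base b at position p (-5..+5, 0 = the
#' edited C).  Flanks containing non-ACGT characters are dropped with a
#' message.  Every column sums to the number of retained flanks.
#'
#' @param flanks character vector of 11-mers.
#' @return list of class \code{composition_matrix}: \code{counts} (4 x 11)
#'   and \code{n_sites}.
#' @export
composition_matrix <- function(flanks) {
  w <- (length(MOTIF_POSITIONS) - 1L) / 2L
  ok <- !grepl("[^ACGT]", flanks) & nchar(flanks) == 2L * w + 1L
  if (any(!ok))
    message("composition_matrix: dropped ", sum(!ok), " flanks")
  flanks <- flanks[ok]
  counts <- matrix(0L, nrow = 4, ncol = 2L * w + 1L,
                   dimnames = list(BASES, as.character(MOTIF_POSITIONS)))
  if (length(flanks)) {
    chars <- matrix(unlist(strsplit(flanks, ""), use.names = FALSE),
                    ncol = 2L * w + 1L, byrow = TRUE)
    for (p in seq_len(ncol(chars)))
      counts[, p] <- tabulate(factor(chars[, p], levels = BASES), 4L)
  }
  structure(list(counts = counts, n_sites = length(flanks)),
            class = "composition_matrix")
}

#' Transcriptome background composition around C residues
#'
#' Aggregates the +/-5 context of every C residue (with a full flank) in
#' every supplied transcript and normalizes each position to proportions.
#'
#' @param transcripts a [transcript_set()].
#' @param window half-window.
#' @return list of class \code{background_matrix}: \code{proportions}
#'   (4 x 11, column-stochastic) and \code{n_contexts}.
#' @export
background_matrix <- function(transcripts, window = 5L) {
  counts <- matrix(0, nrow = 4, ncol = 2L * window + 1L,
                   dimnames = list(BASES, as.character(-window:window)))
  n_ctx <- 0L
  for (i in seq_len(nrow(transcripts))) {
    s <- transcripts$sequence[i]
    chars <- strsplit(s, "")[[1]]
    cpos <- which(chars == "C")
    cpos <- cpos[cpos > window & cpos <= length(chars) - window]
    if (!length(cpos)) next
    n_ctx <- n_ctx + length(cpos)
    for (off in -window:window) {
      b <- chars[cpos + off]
      counts[, as.character(off)] <- counts[, as.character(off)] +
        tabulate(factor(b, levels = BASES), 4L)
    }
  }
  if (n_ctx == 0) stop("no C residue with a full flank in the transcripts")
  props <- sweep(counts, 2, colSums(counts), "/")
  structure(list(proportions = props, n_contexts = n_ctx),
            class = "background_matrix")
}

#' Positional chi-square tests of a composition matrix against background
#'
#' For every position except 0: goodness-of-fit chi-square of the observed
#' 4-vector against n_sites * background proportions, 3 df, upper-tail p.
#' Background proportions of exactly 0 are floored at
#' 1/(4 * n_contexts) so the statistic stays finite (re-normalizing the
#' column), and the floor is reported.  With \code{variant =
#' "independence"} a 4x2 independence chi-square of cluster counts vs
#' background counts is used instead.
#'
#' @param cluster_matrix a [composition_matrix()].
#' @param background a [background_matrix()].
#' @param min_sites minimum n_sites for a valid test (default 20).
#' @param variant "goodness_of_fit" (default) or "independence".
#' @return data.frame: position, chi2, df, p_value, purine_fraction,
#'   dominant_base.
#' @export
test_positions <- function(cluster_matrix, background, min_sites = 20L,
                           variant = c("goodness_of_fit", "independence")) {
  variant <- match.arg(variant)
  n <- cluster_matrix$n_sites
  if (n < min_sites)
    stop("need at least ", min_sites, " sites for positional chi-square")
  pos <- setdiff(MOTIF_POSITIONS, 0L)
  floor_p <- 1 / (4 * background$n_contexts)
  out <- lapply(pos, function(p) {
    obs <- cluster_matrix$counts[, as.character(p)]
    bg <- background$proportions[, as.character(p)]
    if (any(bg == 0 & obs > 0)) {
      message("test_positions: background floor applied at position ", p)
      bg <- pmax(bg, floor_p)
      bg <- bg / sum(bg)
    }
    if (variant == "goodness_of_fit") {
      exp_cnt <- n * bg
      keep <- exp_cnt > 0
      chi2 <- sum((obs[keep] - exp_cnt[keep])^2 / exp_cnt[keep])
      df <- 3
    } else {
      bg_cnt <- round(background$n_contexts * bg)
      tab <- cbind(obs, bg_cnt)
      sr <- rowSums(tab); sc <- colSums(tab)
      expd <- outer(sr, sc) / sum(tab)
      keep <- expd > 0
      chi2 <- sum((tab[keep] - expd[keep])^2 / expd[keep])
      df <- sum(sr > 0) - 1
    }
    data.frame(position = p, chi2 = chi2, df = df,
               p_value = pchisq(chi2, df, lower.tail = FALSE),
               purine_fraction = sum(obs[PURINES]) / sum(obs),
               dominant_base = BASES[which.max(obs)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call the core motif from positional tests
#'
#' Positions are labeled R when significant (p < alpha) with purine
#' fraction >= \code{purine_threshold}, Y for the pyrimidine mirror case,
#' N otherwise; position 0 is always C.  The core is the -1..+1
#' triplet.
#'
#' @param tests result of [test_positions()].
#' @param purine_threshold minimum purine (or pyrimidine) fraction for an
#'   R (or Y) label.
#' @param alpha positional significance level.
#' @return object of class \code{motif_scan}: list with \code{motif}
#'   (11-character IUPAC string), \code{core} (3 characters),
#'   \code{purine_fractions} and \code{tests}.
#' @export
call_core_motif <- function(tests, purine_threshold = 0.6, alpha = 0.05) {
  lab <- setNames(rep("N", length(MOTIF_POSITIONS)),
                  as.character(MOTIF_POSITIONS))
  lab["0"] <- "C"
  for (r in seq_len(nrow(tests))) {
    p <- as.character(tests$position[r])
    if (tests$p_value[r] < alpha) {
      if (tests$purine_fraction[r] >= purine_threshold) lab[p] <- "R"
      else if (1 - tests$purine_fraction[r] >= purine_threshold)
        lab[p] <- "Y"
    }
  }
  motif <- paste(lab, collapse = "")
  core <- paste(lab[as.character(-1:1)], collapse = "")
  structure(list(motif = motif, core = core,
                 purine_fractions = setNames(tests$purine_fraction,
                                             tests$position),
                 tests = tests),
            class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat("motif_scan\n  motif:", x$motif, "\n  core :", x$core, "\n")
  sig <- x$tests[x$tests$p_value < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant positions:",
        paste(sprintf("%+d (p=%.2g)", sig$position, sig$p_value),
              collapse = ", "), "\n")
  } else cat("  no significant positions\n")
  invisible(x)
}

#' One-call motif scan for a set of C-to-U sites
#'
#' Convenience wrapper: extract flanks, build the composition and
#' background matrices, test positions and call the core motif.
#'
#' @param sites C-to-U sites.
#' @param transcripts a [transcript_set()]; also defines the background.
#' @param window half-window (5).
#' @param purine_threshold,alpha see [call_core_motif()].
#' @param min_sites see [test_positions()].
#' @return a \code{motif_scan} object with the composition matrix attached
#'   as \code{$composition}.
#' @export
motif_scan <- function(sites, transcripts, window = 5L,
                       purine_threshold = 0.6, alpha = 0.05,
                       min_sites = 20L) {
  fl <- extract_flanks(sites, transcripts, window)
  cm <- composition_matrix(fl)
  bg <- background_matrix(transcripts, window)
  tests <- test_positions(cm, bg, min_sites = min_sites)
  res <- call_core_motif(tests, purine_threshold, alpha)
  res$composition <- cm
  res$background <- bg
  res
}
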