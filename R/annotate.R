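# Characterization of called sites: region, codon position, synonymy,
# densities, per-amino-acid rates, transcript grouping, RPKM, and
# cross-validation against independent evidence.

#' Region of a site within its transcript
#'
#' Half-open interval membership against the transcript's
#' 5'UTR/CDS/3'UTR partition.
#'
#' @param transcripts a [transcript_set()].
#' @param transcript_id,position site coordinates (0-based), vectorized.
#' @return character vector: "5UTR", "CDS" or "3UTR".
#' @export
assign_region <- function(transcripts, transcript_id, position) {
  i <- match(transcript_id, transcripts$id)
  if (anyNA(i)) stop("unknown transcript")
  if (any(position < 0 | position >= transcripts$length[i]))
    stop("site position outside transcript (invariant breach)")
  ifelse(position < transcripts$cds_start[i], "5UTR",
         ifelse(position < transcripts$cds_end[i], "CDS", "3UTR"))
}

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))  # stops are "*"
})

translate_codon <- function(codon) {
  unname(GENETIC_CODE_TABLE[codon])
}

#' Codon annotation of CDS sites
#'
#' For a CDS site: codon position \code{((pos - cds_start) mod 3) + 1},
#' the reference codon, the alternative codon with the edited base
#' substituted, both translations under the standard genetic code (stop =
#' "*"), and the synonymy flag.  Codons containing N yield NA codon
#' fields.
#'
#' @param transcripts a [transcript_set()].
#' @param sites site data.frame with \code{transcript_id},
#'   \code{position}, \code{alt}; all rows must be CDS sites.
#' @return data.frame with \code{codon_position}, \code{ref_codon},
#'   \code{alt_codon}, \code{ref_aa}, \code{alt_aa}, \code{synonymous}.
#' @export
annotate_codon <- function(transcripts, sites) {
  i <- match(sites$transcript_id, transcripts$id)
  off <- sites$position - transcripts$cds_start[i]
  stopifnot(all(off >= 0), all(sites$position < transcripts$cds_end[i]))
  codon_pos <- (off %% 3L) + 1L
  codon_start <- sites$position - (codon_pos - 1L)          # 0-based
  ref_codon <- substring(transcripts$sequence[i], codon_start + 1L,
                         codon_start + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- sites$alt
  ok <- !grepl("[^ACGT]", ref_codon)
  if (any(!ok))
    message("annotate_codon: ", sum(!ok), " codons contain N, left NA")
  ref_aa <- ifelse(ok, translate_codon(ref_codon), NA_character_)
  alt_aa <- ifelse(ok, translate_codon(alt_codon), NA_character_)
  data.frame(
    codon_position = codon_pos,
    ref_codon = ifelse(ok, ref_codon, NA_character_),
    alt_codon = ifelse(ok, alt_codon, NA_character_),
    ref_aa = ref_aa, alt_aa = alt_aa,
    synonymous = ifelse(ok, ref_aa == alt_aa, NA),
    stringsAsFactors = FALSE
  )
}

#' Annotate called sites with region and codon information
#'
#' @param sites called-site data.frame (e.g. from [call_editing_sites()]).
#' @param transcripts a [transcript_set()].
#' @return \code{annotated_sites} data.frame: input columns plus
#'   \code{region} and, for CDS sites, the codon columns of
#'   [annotate_codon()].
#' @export
annotate_sites <- function(sites, transcripts) {
  out <- as.data.frame(sites)
  out$region <- if (nrow(out)) assign_region(transcripts, out$transcript_id,
                                             out$position) else character(0)
  out$codon_position <- NA_integer_
  out$ref_codon <- NA_character_; out$alt_codon <- NA_character_
  out$ref_aa <- NA_character_; out$alt_aa <- NA_character_
  out$synonymous <- NA
  cds <- which(out$region == "CDS")
  if (length(cds)) {
    cod <- annotate_codon(transcripts, out[cds, , drop = FALSE])
    out[cds, names(cod)] <- cod
  }
  class(out) <- c("annotated_sites", "data.frame")
  out
}

#' Editing density per region and substitution type
#'
#' Density is sites per kilobase: for each region class the denominator is
#' the summed region length (in kb) over all supplied transcripts (or only
#' edited ones with \code{edited_only = TRUE}).
#'
#' @param sites annotated sites (need \code{region}, \code{type_label}).
#' @param transcripts a [transcript_set()].
#' @param edited_only restrict the denominator to transcripts carrying at
#'   least one site.
#' @return data.frame: \code{region}, \code{type_label}, \code{count},
#'   \code{kb}, \code{density}.
#' @export
density_table <- function(sites, transcripts, edited_only = FALSE) {
  tx <- transcripts
  if (edited_only)
    tx <- tx[tx$id %in% unique(sites$transcript_id), , drop = FALSE]
  kb <- c(`5UTR` = sum(tx$utr5_end - tx$utr5_start),
          CDS = sum(tx$cds_end - tx$cds_start),
          `3UTR` = sum(tx$utr3_end - tx$utr3_start)) / 1000
  types <- sort(unique(sites$type_label))
  grid <- expand.grid(region = names(kb), type_label = types,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(r, t)
    sum(sites$region == r & sites$type_label == t),
    grid$region, grid$type_label)
  grid$kb <- kb[grid$region]
  if (any(grid$kb == 0 & grid$count > 0))
    stop("sites in a region class of zero total length")
  grid$density <- ifelse(grid$kb > 0, grid$count / grid$kb, 0)
  rownames(grid) <- NULL
  grid
}

# degeneracy of the standard code: number of codons per amino acid
# (stop "*" has 3)
aa_degeneracy <- function() {
  table(GENETIC_CODE_TABLE)
}

#' Editing events per degenerate codon, by amino acid
#'
#' rate(aa) = (number of events whose reference codon encodes aa) /
#' (number of codons encoding aa in the standard code).  Stop codons are
#' treated as a 21st class ("*", degeneracy 3).  With
#' \code{denominator = "usage"} the denominator is instead the number of
#' occurrences of aa's codons in the supplied transcript CDSs.
#'
#' @param sites annotated sites (CDS rows with \code{ref_aa} are used).
#' @param denominator "degeneracy" (default) or "usage".
#' @param transcripts required for \code{denominator = "usage"}.
#' @return data.frame: \code{aa}, \code{events}, \code{denominator},
#'   \code{rate}.
#' @export
amino_acid_rates <- function(sites, denominator = c("degeneracy", "usage"),
                             transcripts = NULL) {
  denominator <- match.arg(denominator)
  aa_all <- sort(unique(GENETIC_CODE_TABLE))
  ev <- sites$ref_aa[!is.na(sites$ref_aa)]
  events <- vapply(aa_all, function(a) sum(ev == a), 0)
  denom <- if (denominator == "degeneracy") {
    as.numeric(aa_degeneracy()[aa_all])
  } else {
    if (is.null(transcripts)) stop("usage denominator needs transcripts")
    cds <- substring(transcripts$sequence, transcripts$cds_start + 1L,
                     transcripts$cds_end)
    codons <- unlist(lapply(cds, function(s) {
      k <- nchar(s) %/% 3L
      substring(s, 3L * (seq_len(k) - 1L) + 1L, 3L * seq_len(k))
    }))
    usage <- table(factor(translate_codon(codons), levels = aa_all))
    as.numeric(usage)
  }
  data.frame(aa = aa_all, events = events, denominator = denom,
             rate = events / denom, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Group edited transcripts by the regions they are edited in
#'
#' Labels are region-letter sets in fixed order: A = 5'UTR, B = CDS,
#' C = 3'UTR; e.g. "AC" means sites in both UTRs but not the CDS.  When an
#' expression table is supplied, per-group median and mean log2 RPKM are
#' reported.
#'
#' @param sites annotated sites.
#' @param expression optional data.frame with \code{gene_id} and
#'   \code{log2_rpkm} (see [expression_records()]).
#' @return list with \code{genes} (gene_id, group) and \code{summary}
#'   (group, n, plus expression stats when available).
#' @export
group_transcripts <- function(sites, expression = NULL) {
  letter <- c(`5UTR` = "A", CDS = "B", `3UTR` = "C")
  by_gene <- split(sites$region, sites$transcript_id)
  lab <- vapply(by_gene, function(r)
    paste(c("A", "B", "C")[c("A", "B", "C") %in% letter[unique(r)]],
          collapse = ""), "")
  genes <- data.frame(gene_id = names(lab), group = unname(lab),
                      stringsAsFactors = FALSE)
  groups <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  summ <- data.frame(group = groups,
                     n = vapply(groups, function(g) sum(lab == g), 0L),
                     row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(expression)) {
    x <- expression$log2_rpkm[match(genes$gene_id, expression$gene_id)]
    summ$median_log2_rpkm <- vapply(groups, function(g) {
      v <- x[genes$group == g]
      if (length(v) == 0) NA_real_ else median(v, na.rm = TRUE)
    }, 0)
    summ$mean_log2_rpkm <- vapply(groups, function(g) {
      v <- x[genes$group == g]
      if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
  }
  list(genes = genes, summary = summ)
}

#' Per-gene expression records with RPKM and editing-degree adjustment
#'
#' RPKM = count / (length_kb * million mapped reads).  The adjusted
#' expression multiplies RPKM by the gene's mean editing degree, turning
#' expression into an estimate of the number of edited transcripts;
#' unedited genes (no sites) get degree 1.
#'
#' @param counts named vector of raw read counts per gene.
#' @param length_kb named vector of transcript lengths in kb.
#' @param total_mapped_millions library size in millions of mapped reads.
#' @param sites optional annotated sites providing per-gene mean degree.
#' @param pseudocount added to RPKM before log2 (default 0; log2 is NA for
#'   rpkm + pseudocount <= 0).
#' @return data.frame: gene_id, count, length_kb, rpkm, log2_rpkm,
#'   mean_editing_degree, adjusted_expression.
#' @export
expression_records <- function(counts, length_kb, total_mapped_millions,
                               sites = NULL, pseudocount = 0) {
  gene_id <- names(counts)
  stopifnot(!is.null(gene_id), length(length_kb) == length(counts))
  rpkm <- counts / (length_kb * total_mapped_millions)
  deg <- rep(1, length(counts))
  if (!is.null(sites) && nrow(sites) > 0) {
    md <- tapply(sites$degree, sites$transcript_id, mean)
    hit <- match(gene_id, names(md))
    deg[!is.na(hit)] <- md[hit[!is.na(hit)]]
  }
  l2 <- ifelse(rpkm + pseudocount > 0, log2(rpkm + pseudocount), NA_real_)
  data.frame(gene_id = gene_id, count = as.numeric(counts),
             length_kb = as.numeric(length_kb), rpkm = as.numeric(rpkm),
             log2_rpkm = as.numeric(l2), mean_editing_degree = deg,
             adjusted_expression = as.numeric(rpkm) * deg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-validate called sites against independent evidence
#'
#' A site is covered when at least one evidence call exists at its
#' coordinate; it is confirmed when some evidence call there carries the
#' site's alternative base.
#'
#' @param sites called sites.
#' @param evidence evidence data.frame (\code{transcript_id},
#'   \code{position} 0-based, \code{observed_base}), e.g. from
#'   [read_evidence()].
#' @return list: \code{covered}, \code{confirmed},
#'   \code{confirmed_fraction} (NA when nothing is covered), and
#'   \code{per_transcript} rollup of confirmed sites.
#' @export
cross_validate <- function(sites, evidence) {
  if (nrow(sites) == 0 || nrow(evidence) == 0)
    return(list(covered = 0L, confirmed = 0L,
                confirmed_fraction = NA_real_,
                per_transcript = data.frame(transcript_id = character(),
                                            confirmed = integer())))
  skey <- paste(sites$transcript_id, sites$position)
  ekey <- paste(evidence$transcript_id, evidence$position)
  covered <- skey %in% ekey
  conf_key <- paste(evidence$transcript_id, evidence$position,
                    evidence$observed_base)
  confirmed <- paste(skey, sites$alt) %in% conf_key
  roll <- table(sites$transcript_id[confirmed])
  list(covered = sum(covered), confirmed = sum(confirmed),
       confirmed_fraction = if (sum(covered) > 0)
         sum(confirmed) / sum(covered) else NA_real_,
       per_transcript = data.frame(transcript_id = names(roll),
                                   confirmed = as.integer(roll),
                                   row.names = NULL,
                                   stringsAsFactors = FALSE))
}
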