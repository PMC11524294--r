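# Readers/writers for every external format the pipeline touches.  One
# convention is enforced at this boundary: files carry 1-based inclusive
# coordinates, everything in memory is 0-based half-open, and the +/-1
# arithmetic happens here and nowhere else.

#' Write a transcript set as FASTA + GFF3
#'
#' GFF3 features are \code{five_prime_UTR}, \code{CDS} and
#' \code{three_prime_UTR} in 1-based inclusive coordinates on the
#' transcript itself (seqid = transcript id).  Empty UTRs are omitted.
#'
#' @param tx a [transcript_set()].
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transcripts <- function(tx, fasta_path, gff3_path) {
  validate_transcripts(tx)
  seqs <- Biostrings::DNAStringSet(setNames(tx$sequence, tx$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  feat <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    r <- tx[i, ]
    out <- data.frame(seqid = r$id,
                      type = c("five_prime_UTR", "CDS", "three_prime_UTR"),
                      start = c(r$utr5_start, r$cds_start, r$utr3_start) + 1L,
                      end = c(r$utr5_end, r$cds_end, r$utr3_end),
                      stringsAsFactors = FALSE)
    out[out$end >= out$start, , drop = FALSE]  # drop empty intervals
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = feat$seqid,
    ranges = IRanges::IRanges(start = feat$start, end = feat$end),
    type = feat$type,
    phase = ifelse(feat$type == "CDS", 0L, NA_integer_)
  )
  GenomeInfoDb::seqlengths(gr) <- setNames(tx$length, tx$id)[
    GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}

#' Read a transcript set from FASTA + GFF3
#'
#' Converts 1-based inclusive GFF3 features to the internal 0-based
#' half-open frame and enforces the region invariants (contiguous
#' 5'UTR/CDS/3'UTR partition, CDS length divisible by 3).  Transcripts
#' with no UTR feature get the empty intervals.
#'
#' @param fasta_path,gff3_path input paths.
#' @return a [transcript_set()].
#' @export
read_transcripts <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  fdf <- data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                    type = as.character(gr$type),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  pick <- function(id, type, len) {
    rows <- fdf[fdf$seqid == id & fdf$type == type, , drop = FALSE]
    if (nrow(rows) == 0)
      return(if (type == "five_prime_UTR") c(0L, 0L) else c(len, len))
    if (nrow(rows) > 1)
      stop("transcript ", id, ": multiple ", type, " features")
    c(rows$start - 1L, rows$end)       # 1-based inclusive -> 0-based half-open
  }
  cds_start <- integer(length(ids)); cds_end <- integer(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]; len <- Biostrings::width(seqs)[i]
    if (!any(fdf$seqid == id & fdf$type == "CDS"))
      stop("transcript ", id, ": no CDS feature")
    u5 <- pick(id, "five_prime_UTR", 0L)
    cds <- pick(id, "CDS", len)
    u3 <- pick(id, "three_prime_UTR", len)
    if (u5[1] != 0 || u5[2] != cds[1] || cds[2] != u3[1] || u3[2] != len)
      stop("transcript ", id,
           ": UTR/CDS features overlap or leave gaps")
    cds_start[i] <- cds[1]; cds_end[i] <- cds[2]
  }
  transcript_set(id = ids, sequence = as.character(seqs),
                 cds_start = cds_start, cds_end = cds_end)
}

#' Write a pileup table
#'
#' Six tab-separated columns: transcript, 1-based position, reference
#' base, coverage, comma-joined base counts (A,C,G,T order) and mean base
#' quality.
#'
#' @param pileup pileup data.frame as produced by [simulate_pileup()].
#' @param path output path.
#' @export
write_pileup <- function(pileup, path) {
  out <- data.frame(
    transcript = pileup$transcript_id,
    pos = pileup$position + 1L,
    ref = pileup$ref,
    cov = pileup$coverage,
    counts = paste(pileup$A, pileup$C, pileup$G, pileup$T, sep = ","),
    mean_qual = pileup$mean_qual
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a pileup table
#'
#' Validates each row: counts must sum to the coverage column and, when a
#' transcript set is supplied, the reference base must equal the
#' transcript sequence at that position (this guards the DNA-RNA
#' comparison).  Columns on an N reference are skipped with a message.
#'
#' @param path input path.
#' @param transcripts optional [transcript_set()] for reference checking.
#' @return pileup data.frame (0-based positions).
#' @export
read_pileup <- function(path, transcripts = NULL) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "integer", "character", "numeric"))
  if (nrow(raw) == 0)
    return(data.frame(transcript_id = character(), position = integer(),
                      ref = character(), coverage = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), mean_qual = numeric()))
  cnt <- do.call(rbind, lapply(strsplit(raw$counts, ","), as.integer))
  colnames(cnt) <- BASES
  if (any(rowSums(cnt) != raw$cov)) {
    i <- which(rowSums(cnt) != raw$cov)[1]
    stop("pileup row ", i, " (", raw$transcript[i], ":", raw$pos[i],
         "): base counts do not sum to coverage")
  }
  keep <- raw$ref %in% BASES
  if (any(!keep))
    message("read_pileup: skipped ", sum(!keep), " columns on N reference")
  pu <- data.frame(
    transcript_id = raw$transcript[keep], position = raw$pos[keep] - 1L,
    ref = raw$ref[keep], coverage = raw$cov[keep],
    A = cnt[keep, "A"], C = cnt[keep, "C"], G = cnt[keep, "G"],
    T = cnt[keep, "T"],
    mean_qual = raw$mean_qual[keep], stringsAsFactors = FALSE
  )
  if (!is.null(transcripts)) {
    fa_ref <- tx_base(transcripts, pu$transcript_id, pu$position)
    if (any(fa_ref != pu$ref)) {
      i <- which(fa_ref != pu$ref)[1]
      stop("pileup reference mismatch at ", pu$transcript_id[i], ":",
           pu$position[i] + 1L, " (pileup ", pu$ref[i],
           ", FASTA ", fa_ref[i], ")")
    }
  }
  pu
}

SITE_COLUMNS <- c("transcript", "pos", "ref", "alt", "type", "coverage",
                  "edited_count", "degree", "p", "q", "region",
                  "codon_pos", "synonymous")

#' Write called/annotated sites
#'
#' TSV dialect: columns transcript, pos (1-based), ref, alt, type,
#' coverage, edited_count, degree, p, q, region, codon_pos, synonymous.
#' VCF dialect: minimal VCFv4.2 with INFO keys ED (degree), ET (type),
#' RG (region).
#'
#' @param sites site table (0-based \code{position} column internally).
#' @param path output path.
#' @param dialect "tsv" or "vcf".
#' @export
write_sites <- function(sites, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  get0c <- function(nm, default) {
    if (nm %in% names(sites)) sites[[nm]] else rep(default, nrow(sites))
  }
  tab <- data.frame(
    transcript = get0c("transcript_id", character(0)),
    pos = sites$position + 1L,
    ref = sites$ref, alt = sites$alt,
    type = get0c("type_label", NA_character_),
    coverage = sites$coverage,
    edited_count = sites$alt_count,
    degree = get0c("degree", NA_real_),
    p = get0c("p_value", NA_real_), q = get0c("q_value", NA_real_),
    region = get0c("region", NA_character_),
    codon_pos = get0c("codon_position", NA_integer_),
    synonymous = get0c("synonymous", NA),
    stringsAsFactors = FALSE
  )
  if (dialect == "tsv") {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=ED,Number=1,Type=Float,Description=\"Editing degree\">",
             "##INFO=<ID=ET,Number=1,Type=String,Description=\"Editing type\">",
             "##INFO=<ID=RG,Number=1,Type=String,Description=\"Region\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- sprintf("ED=%g;ET=%s;RG=%s", tab$degree, tab$type, tab$region)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    tab$transcript, tab$pos, tab$ref, tab$alt, info)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a sites TSV written by [write_sites()]
#' @param path input path.
#' @return site data.frame with internal column names and 0-based positions.
#' @export
read_sites <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(transcript = "character",
                                   ref = "character", alt = "character",
                                   type = "character",
                                   region = "character"))
  data.frame(
    transcript_id = as.character(tab$transcript), position = tab$pos - 1L,
    ref = tab$ref, alt = tab$alt, type_label = tab$type,
    coverage = tab$coverage, alt_count = tab$edited_count,
    degree = tab$degree, p_value = tab$p, q_value = tab$q,
    region = tab$region, codon_position = tab$codon_pos,
    synonymous = tab$synonymous, stringsAsFactors = FALSE
  )
}

#' Write / read an expression matrix (genes x samples TSV)
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @rdname expression_io
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_expression <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  m
}

#' Write / read a gene label table
#'
#' Columns: gene_id, go_terms (semicolon-joined, may be empty),
#' endosymbiont (0/1), ppr (0/1), edited (0/1).
#'
#' @param labels label data.frame.
#' @param path file path.
#' @rdname labels_io
#' @export
write_labels <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname labels_io
#' @export
read_labels <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character",
                                   go_terms = "character"))
  tab$go_terms[is.na(tab$go_terms)] <- ""
  tab
}

#' Write / read a planted-site ground-truth table (1-based positions)
#' @param planted planted-site data.frame from [plant_sites()].
#' @param path file path.
#' @rdname truth_io
#' @export
write_truth <- function(planted, path) {
  out <- planted
  out$position <- out$position + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_io
#' @export
read_truth <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(transcript_id = "character",
                                   ref_base = "character",
                                   alt_base = "character"))
  tab$position <- tab$position - 1L
  tab
}

#' Read independent evidence calls (EST-style), 1-based positions in file
#' @param path TSV with columns transcript_id, position, observed_base.
#' @return data.frame with 0-based positions.
#' @export
read_evidence <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(transcript_id = "character",
                                   position = "integer",
                                   observed_base = "character"))
  stopifnot(all(tab$observed_base %in% BASES))
  tab$position <- tab$position - 1L
  tab
}
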