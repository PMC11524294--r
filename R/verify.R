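# Worked-example verification: recompute, through the package's own
# operations, the summary quantities of the published P. trichocarpa
# nuclear RNA-editing survey from its printed tables (bundled under
# extdata), and compare to the printed values.

fixture_path <- function(name, dir = NULL) {
  p <- if (is.null(dir)) system.file("extdata", name, package = "nucredit")
  else file.path(dir, name)
  if (!nzchar(p) || !file.exists(p)) stop("missing fixture: ", name)
  p
}

read_printed_counts <- function(dir = NULL) {
  tab <- read.table(fixture_path("ptrichocarpa_printed_counts.tsv", dir),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(tab$value, tab$key)
}

#' Recompute the bundled worked examples and compare to printed values
#'
#' Each check rebuilds one printed summary statistic of the reference
#' survey from its raw printed inputs using package operations:
#' region-count bookkeeping, the four-type CDS total, the
#' endosymbiont-stratum edited fraction (via [endosymbiont_fisher()] on a
#' reconstructed label table), GO-category edited percentages (via
#' [go_enrichment()]), the EST confirmation fraction (via
#' [cross_validate()] on a reconstructed evidence set), codon-position and
#' type tallies of the A. thaliana chloroplast site table, and the
#' cluster-table totals (via [cluster_report()]).
#'
#' @param dir optional directory holding the fixture files (defaults to
#'   the installed package's extdata).
#' @return data.frame of class \code{fixture_report}: target, value
#'   (recomputed), expected (printed), pass.
#' @export
verify_fixtures <- function(dir = NULL) {
  pc <- read_printed_counts(dir)
  rows <- list()
  add <- function(target, value, expected, tol = 0) {
    rows[[length(rows) + 1]] <<- data.frame(
      target = target, value = value, expected = expected,
      pass = abs(value - expected) <= tol, stringsAsFactors = FALSE)
  }

  # 1. region counts sum to the total site count
  add("region_site_total",
      pc["utr5_sites"] + pc["cds_sites"] + pc["utr3_sites"],
      pc["total_sites"])

  # 2. four dominant types sum to the printed CDS four-type total
  add("cds_four_type_total",
      pc["cds_a_to_g"] + pc["cds_g_to_a"] + pc["cds_c_to_u"] +
        pc["cds_u_to_c"],
      pc["cds_four_type_total"])

  # 3. endosymbiont stratum edited fraction, via the 2x2 construction
  n_endo <- pc["endo_genes"]; k_endo <- pc["endo_edited"]
  n_other <- 35000  # stratum size is not printed; the fraction under
                    # test does not depend on it
  k_other <- round(n_other * pc["other_edited_pct"] / 100)
  labs <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_endo + n_other)),
    endosymbiont = rep(c(1L, 0L), c(n_endo, n_other)),
    edited = c(rep(c(1L, 0L), c(k_endo, n_endo - k_endo)),
               rep(c(1L, 0L), c(k_other, n_other - k_other))))
  ef <- endosymbiont_fisher(labs)
  add("endosymbiont_edited_pct", round(100 * ef$fraction_endo, 1),
      pc["endo_edited_pct"], tol = 0.05)

  # 4. GO percentages via go_enrichment on reconstructed term universes
  go_pct <- function(k, size) {
    u <- data.frame(gene_id = sprintf("t%04d", seq_len(2 * size)),
                    go_terms = rep(c("GO:X", ""), c(size, size)),
                    edited = c(rep(c(1L, 0L), c(k, size - k)),
                               integer(size)))
    r <- go_enrichment(u, alpha = 1)
    r$edited_pct[r$term == "GO:X"]
  }
  add("go_cul4_edited_pct",
      round(go_pct(pc["go_cul4_k"], pc["go_cul4_size"]), 1),
      pc["go_cul4_pct"], tol = 0.05)
  add("go_exocyst_edited_pct",
      round(go_pct(pc["go_exocyst_k"], pc["go_exocyst_size"]), 1),
      pc["go_exocyst_pct"], tol = 0.05)

  # 5. EST confirmation fraction via cross_validate on a reconstructed
  #    covered-site/evidence pair
  n_cov <- pc["est_covered"]; n_conf <- pc["est_confirmed"]
  sites <- data.frame(transcript_id = "t", position = seq_len(n_cov) - 1L,
                      ref = "C", alt = "T", stringsAsFactors = FALSE)
  evidence <- data.frame(
    transcript_id = "t", position = seq_len(n_cov) - 1L,
    observed_base = rep(c("T", "C"), c(n_conf, n_cov - n_conf)),
    stringsAsFactors = FALSE)
  cv <- cross_validate(sites, evidence)
  add("est_confirmed_pct", round(100 * cv$confirmed_fraction, 1),
      pc["est_confirmed_pct"], tol = 0.05)

  # 6. A. thaliana chloroplast table tallies
  chl <- read.table(fixture_path("athaliana_chloroplast_sites.tsv", dir),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(dna = "character", rna = "character"))
  add("chloroplast_codon2_count", sum(chl$codon_position == 2),
      pc["chloroplast_codon2_count"])
  add("chloroplast_c_to_u_count",
      sum(edit_type_label(chl$dna, chl$rna) == "C-to-U"),
      pc["chloroplast_c_to_u_count"])

  # 7. cluster-table totals via cluster_report on a reconstructed
  #    membership
  tab1 <- read.table(fixture_path("ppr_cluster_table.tsv", dir),
                     header = TRUE, sep = "\t")
  memb <- do.call(rbind, lapply(seq_len(nrow(tab1)), function(i) {
    n_e <- tab1$n_edited_genes[i]; n_p <- tab1$n_ppr[i]
    data.frame(cluster = tab1$cluster[i],
               gene_id = sprintf("c%d_g%03d", tab1$cluster[i],
                                 seq_len(n_e + n_p)),
               ppr = rep(c(0L, 1L), c(n_e, n_p)))
  }))
  labs1 <- data.frame(gene_id = memb$gene_id, ppr = memb$ppr,
                      edited = 1L - memb$ppr)
  rep1 <- cluster_report(memb[, c("cluster", "gene_id")], labs1)
  tot <- rep1[rep1$cluster == "total", ]
  add("cluster_edited_total", tot$n_edited_genes, pc["cluster_edited_total"])
  add("cluster_ppr_total", tot$n_ppr, pc["cluster_ppr_total"])

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fixture_report", "data.frame")
  out
}

#' @export
print.fixture_report <- function(x, ...) {
  status <- ifelse(x$pass, "ok", "FAIL")
  cat("fixture verification:", sum(x$pass), "of", nrow(x), "checks pass\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-28s value=%g expected=%g\n", status[i],
                x$target[i], x$value[i], x$expected[i]))
  invisible(x)
}
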