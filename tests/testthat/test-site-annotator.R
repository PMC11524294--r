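test_that("region assignment respects half-open boundaries", {
  tx <- transcript_set(id = "t1", sequence = strrep("ACGT", 100),
                       cds_start = 100L, cds_end = 340L)
  expect_equal(assign_region(tx, "t1", 99L), "5UTR")   # last 5'UTR base
  expect_equal(assign_region(tx, "t1", 100L), "CDS")   # first CDS base
  expect_equal(assign_region(tx, "t1", 339L), "CDS")
  expect_equal(assign_region(tx, "t1", 340L), "3UTR")
  expect_error(assign_region(tx, "t1", 400L), "outside")
  # empty 5'UTR: position 0 is CDS
  tx0 <- transcript_set(id = "t1", sequence = strrep("ATGAAACCCTAG", 5),
                        cds_start = 0L, cds_end = 60L)
  expect_equal(assign_region(tx0, "t1", 0L), "CDS")
})

test_that("codon annotation handles degeneracy, missense and stop gain", {
  # CDS: ATG GCC CAT CGA ; transcript has a 2 nt 5'UTR
  tx <- transcript_set(id = "t1", sequence = paste0("AA", "ATGGCCCATCGA", "A", "CC"),
                       cds_start = 2L, cds_end = 14L)
  site <- function(pos, alt) data.frame(transcript_id = "t1",
                                        position = pos, alt = alt)
  # C>T at codon 2 position 3: GCC -> GCT, Ala -> Ala, synonymous
  a <- annotate_codon(tx, site(7L, "T"))
  expect_equal(a$codon_position, 3L)
  expect_equal(a$ref_codon, "GCC"); expect_equal(a$alt_codon, "GCT")
  expect_equal(a$ref_aa, "A"); expect_true(a$synonymous)
  # C>T at codon 3 position 1: CAT -> TAT, His -> Tyr
  b <- annotate_codon(tx, site(8L, "T"))
  expect_equal(b$codon_position, 1L)
  expect_equal(b$ref_aa, "H"); expect_equal(b$alt_aa, "Y")
  expect_false(b$synonymous)
  # C>T at codon 4 position 1: CGA -> TGA, Arg -> stop
  d <- annotate_codon(tx, site(11L, "T"))
  expect_equal(d$ref_aa, "R"); expect_equal(d$alt_aa, "*")
  expect_false(d$synonymous)
})

test_that("synonymy agrees with a translate-and-compare oracle over all 64 codons", {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  # transcript = ATG + all 64 codons + TAA, no UTRs: CDS length 198+
  seq <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  tx <- transcript_set(id = "t1", sequence = seq, cds_start = 0L,
                       cds_end = nchar(seq))
  gc <- nucredit:::GENETIC_CODE_TABLE
  for (cp in 1:3) {
    pos <- 3L + 3L * (seq_along(codons) - 1L) + (cp - 1L)
    ref <- substring(seq, pos + 1L, pos + 1L)
    alt <- c(A = "C", C = "T", G = "A", T = "G")[ref]  # arbitrary edit
    ann <- annotate_codon(tx, data.frame(transcript_id = "t1",
                                         position = pos, alt = unname(alt)))
    expect_equal(ann$codon_position, rep(cp, 64))
    expect_equal(ann$ref_codon, codons)
    # oracle: substitute and translate independently
    alt_codon <- codons
    substr(alt_codon, cp, cp) <- unname(alt)
    expect_equal(ann$synonymous,
                 unname(gc[codons] == gc[alt_codon]))
  }
  # every position-3 edit of a 4-fold degenerate codon is synonymous
  deg4 <- names(table(substr(names(gc), 1, 2))[
    tapply(gc, substr(names(gc), 1, 2), function(x) length(unique(x)) == 1)])
  is4 <- substr(codons, 1, 2) %in% deg4
  pos3 <- 3L + 3L * (seq_along(codons) - 1L) + 2L
  ref3 <- substring(seq, pos3 + 1L, pos3 + 1L)
  alt3 <- c(A = "C", C = "T", G = "A", T = "G")[ref3]
  ann3 <- annotate_codon(tx, data.frame(transcript_id = "t1",
                                        position = pos3,
                                        alt = unname(alt3)))
  expect_true(all(ann3$synonymous[is4]))
})

test_that("density is count per kilobase and scales inversely with length", {
  tx <- transcript_set(id = c("t1", "t2"),
                       sequence = c(paste0(strrep("A", 500),
                                           "ATG", strrep("AAC", 332), "TAA",
                                           strrep("G", 500)),
                                    paste0(strrep("A", 500),
                                           "ATG", strrep("AAC", 332), "TAA",
                                           strrep("G", 500))),
                       cds_start = c(500L, 500L), cds_end = c(1502L, 1502L))
  # 6 CDS sites over 2004 nt CDS total -> ~3 per kb; exact on 2000
  sites <- data.frame(transcript_id = "t1",
                      position = 500L + 3L * (0:5), ref = "A", alt = "G",
                      type_label = "A-to-G",
                      region = "CDS", stringsAsFactors = FALSE)
  dt <- density_table(sites, tx)
  cds_row <- dt[dt$region == "CDS" & dt$type_label == "A-to-G", ]
  expect_equal(cds_row$count, 6)
  expect_equal(cds_row$density, 6 / (2 * 1002 / 1000))
  # count = density * kb for every cell
  expect_equal(dt$count, dt$density * dt$kb)
  # restricting to edited transcripts halves the denominator
  dt_ed <- density_table(sites, tx, edited_only = TRUE)
  ed_row <- dt_ed[dt_ed$region == "CDS" & dt_ed$type_label == "A-to-G", ]
  expect_equal(ed_row$density, 2 * cds_row$density)
})

test_that("amino-acid rates divide events by codon-table degeneracy", {
  sites <- data.frame(ref_aa = c(rep("D", 782), rep("W", 31), rep("*", 12)))
  r <- amino_acid_rates(sites)
  expect_equal(r$rate[r$aa == "D"], 391)   # degeneracy 2
  expect_equal(r$rate[r$aa == "W"], 31)    # degeneracy 1
  expect_equal(r$rate[r$aa == "*"], 4)     # 3 stop codons
  expect_equal(r$rate[r$aa == "F"], 0)
  # one event per codon gives rate 1 for every amino acid and stop
  all64 <- data.frame(ref_aa = unname(nucredit:::GENETIC_CODE_TABLE))
  r1 <- amino_acid_rates(all64)
  expect_true(all(r1$rate == 1))
})

test_that("transcript grouping composes region letters in A<B<C order", {
  sites <- data.frame(
    transcript_id = c("g1", "g2", "g2", "g3", "g3", "g3", "g4"),
    region = c("3UTR", "5UTR", "3UTR", "5UTR", "CDS", "3UTR", "CDS"))
  g <- group_transcripts(sites)
  lab <- setNames(g$genes$group, g$genes$gene_id)
  expect_equal(unname(lab[c("g1", "g2", "g3", "g4")]),
               c("C", "AC", "ABC", "B"))
  # group sizes partition the edited genes
  expect_equal(sum(g$summary$n), 4)
})

test_that("expression records obey the RPKM and adjustment identities", {
  sites <- data.frame(transcript_id = c("g1", "g1"), degree = c(0.2, 0.6))
  er <- expression_records(counts = c(g1 = 1000, g2 = 500),
                           length_kb = c(2, 1),
                           total_mapped_millions = 10,
                           sites = sites)
  expect_equal(er$rpkm, c(1000 / (2 * 10), 500 / (1 * 10)))
  expect_equal(er$mean_editing_degree, c(0.4, 1))  # mean(0.2, 0.6); unedited = 1
  expect_equal(er$adjusted_expression, er$rpkm * er$mean_editing_degree)
  expect_equal(er$log2_rpkm, log2(er$rpkm))
})

test_that("cross-validation counts covered and confirmed sites", {
  sites <- data.frame(transcript_id = c("t1", "t1", "t2"),
                      position = c(5L, 9L, 3L), ref = "C", alt = "T")
  ev <- data.frame(transcript_id = c("t1", "t1", "t9"),
                   position = c(5L, 9L, 1L),
                   observed_base = c("T", "C", "T"))
  cv <- cross_validate(sites, ev)
  expect_equal(cv$covered, 2)
  expect_equal(cv$confirmed, 1)
  expect_equal(cv$confirmed_fraction, 0.5)
  # no evidence: fraction NA
  expect_true(is.na(cross_validate(sites, ev[0, ])$confirmed_fraction))
  # evidence all reference: fraction 0
  ev_ref <- transform(ev, observed_base = "C")
  expect_equal(cross_validate(sites, ev_ref)$confirmed_fraction, 0)
})

test_that("annotated regions partition the called sites", {
  cfg <- sim_config(n_transcripts = 10, n_sites = 150, seed = 41)
  tx <- generate_transcripts(cfg)
  pu <- simulate_pileup(tx, plant_sites(tx, cfg), cfg)
  ann <- annotate_sites(call_editing_sites(pu), tx)
  expect_equal(sum(table(ann$region)), nrow(ann))
  expect_true(all(ann$region %in% c("5UTR", "CDS", "3UTR")))
  # codon fields present iff CDS
  expect_true(all(is.na(ann$codon_position[ann$region != "CDS"])))
  expect_true(all(!is.na(ann$codon_position[ann$region == "CDS"])))
  expect_equal(ann$synonymous[ann$region == "CDS"],
               (ann$ref_aa == ann$alt_aa)[ann$region == "CDS"])
})
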