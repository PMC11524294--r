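test_that("generated transcripts have valid structure and honor length ranges", {
  cfg <- sim_config(n_transcripts = 15, cds_len = c(300L, 300L), seed = 2)
  tx <- generate_transcripts(cfg)
  expect_s3_class(tx, "transcript_set")
  expect_equal(nrow(tx), 15)
  expect_true(all(tx$cds_end - tx$cds_start == 300))
  cds <- substring(tx$sequence, tx$cds_start + 1, tx$cds_end)
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  # no internal in-frame stop in any CDS
  expect_false(any(vapply(cds, nucredit:::has_internal_stop, TRUE)))
  expect_true(all(tx$utr5_end - tx$utr5_start >= cfg$utr5_len[1]))
  expect_true(all(tx$utr3_end - tx$utr3_start <= cfg$utr3_len[2]))
})

test_that("degenerate UTR ranges give pure-CDS transcripts", {
  cfg <- sim_config(n_transcripts = 4, utr5_len = c(0L, 0L),
                    utr3_len = c(0L, 0L), cds_len = c(90L, 90L), seed = 1)
  tx <- generate_transcripts(cfg)
  expect_true(all(tx$cds_start == 0 & tx$cds_end == tx$length))
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_transcripts = 6, n_sites = 30, seed = 42)
  run <- function() {
    tx <- generate_transcripts(cfg)
    pl <- plant_sites(tx, cfg)
    tx <- embed_motif_context(tx, pl, cfg)$transcripts
    pu <- simulate_pileup(tx, pl, cfg)
    ex <- simulate_expression(cfg)
    la <- simulate_annotations(sim_config(ann_n_endo = 50, ann_n_other = 50,
                                          seed = 42))
    f <- tempfile(); g <- tempfile(); p <- tempfile()
    write_transcripts(tx, f, g)
    write_pileup(pu, p)
    list(fa = readLines(f), gff = readLines(g), pu = readLines(p),
         ex = ex, la = la)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})

test_that("planted sites sit on matching reference bases at unique coordinates", {
  cfg <- sim_config(n_transcripts = 10, n_sites = 100, seed = 9)
  tx <- generate_transcripts(cfg)
  pl <- plant_sites(tx, cfg)
  expect_equal(nrow(pl), 100)
  expect_equal(anyDuplicated(paste(pl$transcript_id, pl$position)), 0)
  expect_true(all(pl$ref_base != pl$alt_base))
  expect_equal(nucredit:::tx_base(tx, pl$transcript_id, pl$position),
               pl$ref_base)
  # planted sites keep a full +/-5 flank
  len <- tx$length[match(pl$transcript_id, tx$id)]
  expect_true(all(pl$position >= 5 & pl$position <= len - 6))
})

test_that("point-mass weights and degenerate degree ranges are honored", {
  cfg <- sim_config(n_transcripts = 5, n_sites = 40, seed = 3,
                    editing_types = point_weights("C>T"),
                    degree_range = c(0.42, 0.42))
  pl <- plant_sites(generate_transcripts(cfg), cfg)
  expect_true(all(pl$ref_base == "C" & pl$alt_base == "T"))
  expect_true(all(pl$true_degree == 0.42))
})

test_that("planting more sites than positions errors", {
  cfg <- sim_config(n_transcripts = 1, utr5_len = c(0L, 0L),
                    utr3_len = c(0L, 0L), cds_len = c(30L, 30L),
                    n_sites = 1000, seed = 1)
  tx <- generate_transcripts(cfg)
  expect_error(plant_sites(tx, cfg), "exceeds")
})

test_that("pileup counts always sum to coverage and respect the noise-free limit", {
  cfg <- sim_config(n_transcripts = 3, n_sites = 0, error_rate = 0,
                    coverage_mean = 40, seed = 4)
  tx <- generate_transcripts(cfg)
  pu <- simulate_pileup(tx, plant_sites(tx, cfg), cfg)
  cnt <- as.matrix(pu[, c("A", "C", "G", "T")])
  expect_true(all(rowSums(cnt) == pu$coverage))
  expect_true(all(pu$coverage >= 1))
  # error_rate 0, nothing planted: every column is 100% reference
  ref_count <- cnt[cbind(seq_len(nrow(pu)), match(pu$ref, c("A","C","G","T")))]
  expect_true(all(ref_count == pu$coverage))
})

test_that("a degree-1 site under zero error has alt count equal to coverage", {
  cfg <- sim_config(n_transcripts = 2, n_sites = 10, error_rate = 0,
                    degree_range = c(1, 1), seed = 5,
                    editing_types = point_weights("C>T"))
  tx <- generate_transcripts(cfg)
  pl <- plant_sites(tx, cfg)
  pu <- simulate_pileup(tx, pl, cfg)
  key <- paste(pu$transcript_id, pu$position)
  at <- pu[match(paste(pl$transcript_id, pl$position), key), ]
  expect_true(all(at$T == at$coverage))
})

test_that("planted degrees are recovered within the binomial tail bound", {
  # coverage_mean 1000, degree 0.5: P(|phat - 0.5| > 0.05) is < 1%
  # (normal tail ~ 2*pnorm(-0.05/sqrt(.25/900)) ~ 0.0027), so over 200
  # sites at most a few columns may fall outside
  cfg <- sim_config(n_transcripts = 20, n_sites = 200,
                    coverage_mean = 1000, degree_range = c(0.5, 0.5),
                    error_rate = 0, seed = 6)
  tx <- generate_transcripts(cfg)
  pl <- plant_sites(tx, cfg)
  pu <- simulate_pileup(tx, pl, cfg)
  key <- paste(pu$transcript_id, pu$position)
  at <- pu[match(paste(pl$transcript_id, pl$position), key), ]
  alt_col <- c(A = "A", C = "C", G = "G", T = "T")[pl$alt_base]
  frac <- mapply(function(r, b) at[r, b], seq_len(nrow(at)), alt_col) /
    at$coverage
  expect_gt(mean(abs(frac - 0.5) <= 0.05), 0.99)
})

test_that("motif embedding rewrites eligible flanks to purines", {
  cfg <- sim_config(n_transcripts = 10, n_sites = 80, motif_prob = 1,
                    seed = 7, editing_types = point_weights("C>T"))
  tx <- generate_transcripts(cfg)
  pl <- plant_sites(tx, cfg)
  em <- embed_motif_context(tx, pl, cfg)
  up <- nucredit:::tx_base(em$transcripts, pl$transcript_id, pl$position - 1)
  dn <- nucredit:::tx_base(em$transcripts, pl$transcript_id, pl$position + 1)
  purine_flanked <- up %in% c("A", "G") & dn %in% c("A", "G")
  # every site is either rewritten or skipped (adjacent planted site /
  # unavoidable stop), and rewrites always leave purine flanks
  expect_equal(em$n_rewritten + em$n_skipped, nrow(pl))
  expect_gte(sum(purine_flanked), em$n_rewritten)
  # the edited base itself is untouched
  expect_true(all(nucredit:::tx_base(em$transcripts, pl$transcript_id,
                                     pl$position) == "C"))
  # no internal in-frame stop introduced
  cds <- substring(em$transcripts$sequence, em$transcripts$cds_start + 1,
                   em$transcripts$cds_end)
  expect_false(any(vapply(cds, nucredit:::has_internal_stop, TRUE)))
})

test_that("motif_prob 0 leaves flank composition at background", {
  cfg <- sim_config(n_transcripts = 20, n_sites = 300, motif_prob = 0,
                    seed = 8, editing_types = point_weights("C>T"))
  tx <- generate_transcripts(cfg)
  pl <- plant_sites(tx, cfg)
  em <- embed_motif_context(tx, pl, cfg)
  expect_identical(em$transcripts$sequence, tx$sequence)
  up <- nucredit:::tx_base(tx, pl$transcript_id, pl$position - 1)
  # purine fraction ~ background (~0.5 under the uniform generator);
  # 3.5 sigma binomial band around 0.5 at n = 300 is +/- 0.10
  expect_lt(abs(mean(up %in% c("A", "G")) - 0.5), 0.10)
})

test_that("expression simulator plants the requested correlation structure", {
  cfg <- sim_config(n_clusters = 2, n_samples = 1000,
                    within_cluster_rho = 0.9, seed = 10)
  roles <- make_gene_roles(cfg, ppr_per_cluster = 1, targets_per_cluster = 4)
  expr <- simulate_expression(cfg, roles)
  rho <- cor(t(expr), method = "spearman")
  within <- rho[1:5, 1:5][upper.tri(diag(5))]
  between <- rho[1:5, 6:10]
  # null Spearman var ~ 1/(n-1): |rho| < 0.1 is > 3 sigma at n = 1000
  expect_lt(median(abs(between)), 0.1)
  expect_true(all(within > 0.7))
  expect_lt(abs(mean(within) - 0.9), 0.06)
})

test_that("identical rank orders arise at within_cluster_rho = 1", {
  cfg <- sim_config(n_clusters = 1, n_samples = 50,
                    within_cluster_rho = 1, seed = 11)
  roles <- make_gene_roles(cfg, ppr_per_cluster = 1, targets_per_cluster = 4)
  expr <- simulate_expression(cfg, roles)
  rk <- apply(expr, 1, rank)
  expect_true(all(apply(rk, 1, function(r) length(unique(r)) == 1)))
})

test_that("expression simulator refuses unstable sample counts", {
  cfg <- sim_config(n_samples = 4, seed = 1)
  expect_error(simulate_expression(cfg), "unstable")
})

test_that("annotation simulator plants recoverable stratum fractions", {
  cfg <- sim_config(ann_n_endo = 2000, ann_n_other = 8000,
                    ann_edited_frac_endo = 0.273,
                    ann_edited_frac_other = 0.195, seed = 12)
  labs <- simulate_annotations(cfg)
  expect_equal(nrow(labs), 10000)
  f_endo <- mean(labs$edited[labs$endosymbiont == 1])
  f_other <- mean(labs$edited[labs$endosymbiont == 0])
  expect_lt(abs(f_endo - 0.273), 0.04)
  expect_lt(abs(f_other - 0.195), 0.02)
})

test_that("planted-site tables round-trip losslessly", {
  cfg <- sim_config(n_transcripts = 5, n_sites = 25, seed = 13)
  pl <- plant_sites(generate_transcripts(cfg), cfg)
  f <- tempfile()
  write_truth(pl, f)
  back <- read_truth(f)
  rownames(pl) <- NULL
  expect_equal(back, pl)
})
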