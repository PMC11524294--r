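test_that("read filter enforces seed perfection and the mismatch budget", {
  pol <- read_filter_policy()
  expect_true(filter_read(list(length = 68, mismatch_positions = integer(0)),
                          pol)$accept)
  # mismatch inside the 22 nt seed
  r <- filter_read(list(length = 68, mismatch_positions = 10L), pol)
  expect_false(r$accept); expect_equal(r$reason, "seed_mismatch")
  # 4 mismatches beyond the seed exceed the budget of 3
  r <- filter_read(list(length = 68, mismatch_positions = c(25L, 30L, 40L, 50L)),
                   pol)
  expect_false(r$accept); expect_equal(r$reason, "too_many_edits")
  # exactly 3 beyond the seed is acceptable
  expect_true(filter_read(list(length = 68,
                               mismatch_positions = c(25L, 30L, 40L)),
                          pol)$accept)
  r <- filter_read(list(length = 20, mismatch_positions = integer(0)), pol)
  expect_false(r$accept); expect_equal(r$reason, "short")
})

make_column <- function(ref = "C", counts = c(A = 0, C = 60, G = 0, T = 0),
                        qual = 30) {
  data.frame(transcript_id = "t1", position = 10L, ref = ref,
             coverage = sum(counts), A = counts["A"], C = counts["C"],
             G = counts["G"], T = counts["T"], mean_qual = qual,
             row.names = NULL)
}

test_that("candidate collection applies the 50-read and quality floors", {
  pol <- read_filter_policy()
  expect_equal(nrow(collect_candidates(
    make_column(counts = c(A = 0, C = 34, G = 0, T = 15)), pol)), 0)
  cand <- collect_candidates(
    make_column(counts = c(A = 0, C = 60, G = 0, T = 15)), pol)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$alt, "T")
  expect_equal(cand$alt_count, 15)
  expect_equal(cand$error_rate, 1e-3)    # Phred 30
  # low-quality column dropped
  expect_equal(nrow(collect_candidates(
    make_column(counts = c(A = 0, C = 60, G = 0, T = 15), qual = 15), pol)), 0)
  # two alternative bases give two candidates
  cand2 <- collect_candidates(
    make_column(counts = c(A = 0, C = 82, G = 8, T = 10)), pol)
  expect_equal(sort(cand2$alt), c("G", "T"))
  # a global error rate overrides the quality-derived one
  cand3 <- collect_candidates(
    make_column(counts = c(A = 0, C = 60, G = 0, T = 15)), pol,
    error_rate = 0.01)
  expect_equal(cand3$error_rate, 0.01)
})

test_that("fisher_error_test equals brute-force hypergeometric enumeration", {
  # spec'd behaviors
  expect_equal(fisher_error_test(0, 50, 0.003), 1)
  # saturated table [[50,0],[0,50]]: exact tail is 1/choose(100,50)
  expect_equal(fisher_error_test(50, 50, 0.003), 1 / choose(100, 50),
               tolerance = 1e-12)
  expect_lt(fisher_error_test(50, 50, 0.003), 1e-29)
  # the [[10,90],[1,99]] table, expected count 1 at error 0.03
  expect_equal(fisher_error_test(10, 100, 0.03),
               enum_fisher_greater(10, 90, 1, 99), tolerance = 1e-12)
  expect_equal(fisher_error_test(10, 100, 0.03), 0.004829058,
               tolerance = 1e-7)
  # random tables with coverage <= 200 against enumeration and fisher.test
  set.seed(101)
  for (i in 1:60) {
    n <- sample(50:200, 1)
    a <- sample(0:min(n, 30), 1)
    e_rate <- runif(1, 1e-4, 0.2)
    e <- round(n * e_rate / 3)
    p <- fisher_error_test(a, n, e_rate)
    expect_equal(p, enum_fisher_greater(a, n - a, e, n - e),
                 tolerance = 1e-10)
    expect_equal(p, fisher.test(matrix(c(a, n - a, e, n - e), 2,
                                       byrow = TRUE),
                                alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  expect_error(fisher_error_test(10, 5, 0.01), "exceeds")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_fdr(0.04), 0.04)                       # m = 1
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))                    # min_j p_j m/j
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))         # ties
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  # hand-applied step-up on a scrambled vector
  p <- c(0.30, 0.001, 0.04, 0.012)
  m <- 4; o <- order(p)
  q_hand <- numeric(m)
  q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  q_hand[o] <- pmin(1, q_sorted)
  expect_equal(adjust_fdr(p), q_hand)
})

test_that("site calling keeps q strictly below alpha and labels types", {
  cand <- data.frame(
    transcript_id = "t1", position = c(1L, 2L, 3L), ref = "C", alt = "T",
    coverage = 100L, alt_count = c(30L, 1L, 0L), error_rate = 0.001)
  sites <- call_sites(cand)
  expect_equal(sites$position, 1L)
  expect_equal(sites$type_label, "C-to-U")
  expect_equal(sites$degree, 0.30)
  # a q exactly at alpha is excluded
  pol <- read_filter_policy(alpha = 0.05)
  cand1 <- cand[1, ]
  p1 <- fisher_error_test(30, 100, 0.001)
  pol_exact <- read_filter_policy(alpha = p1)  # alpha == q of the only site
  expect_equal(nrow(call_sites(cand1, pol_exact)), 0)
})

test_that("planted sites are recovered with unbiased degrees", {
  cfg <- sim_config(n_transcripts = 25, n_sites = 500, coverage_mean = 100,
                    degree_range = c(0.2, 0.8), seed = 31)
  tx <- generate_transcripts(cfg)
  pl <- plant_sites(tx, cfg)
  pu <- simulate_pileup(tx, pl, cfg)
  calls <- call_editing_sites(pu)
  tkey <- paste(pl$transcript_id, pl$position, pl$alt_base)
  ckey <- paste(calls$transcript_id, calls$position, calls$alt)
  sens <- mean(tkey %in% ckey)
  expect_gte(sens, 0.95)
  hit <- match(tkey, ckey)
  err <- calls$degree[hit[!is.na(hit)]] - pl$true_degree[!is.na(hit)]
  expect_lt(abs(mean(err)), 0.02)
})

test_that("call counts are monotone in alpha and coverage threshold", {
  cfg <- sim_config(n_transcripts = 10, n_sites = 100, coverage_mean = 60,
                    degree_range = c(0.05, 0.5), seed = 32)
  tx <- generate_transcripts(cfg)
  pu <- simulate_pileup(tx, plant_sites(tx, cfg), cfg)
  n_alpha <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a)
    nrow(call_editing_sites(pu, read_filter_policy(alpha = a))), 0L)
  expect_true(all(diff(n_alpha) <= 0))
  n_cov <- vapply(c(20L, 50L, 80L), function(mc)
    nrow(collect_candidates(pu, read_filter_policy(min_coverage = mc))), 0L)
  expect_true(all(diff(n_cov) <= 0))
})

test_that("null pileups rarely produce any call (empirical FDR control)", {
  # 200 replicates of a 600-column null pileup with the caller's error
  # model matched to the simulator's
  cfg <- sim_config(n_transcripts = 2, utr5_len = c(50L, 50L),
                    cds_len = c(450L, 450L), utr3_len = c(100L, 100L),
                    n_sites = 0, coverage_mean = 60, error_rate = 0.001,
                    seed = 1)
  tx <- generate_transcripts(cfg)
  empty <- plant_sites(tx, cfg)
  hits <- vapply(1:200, function(r) {
    cfg_r <- cfg; cfg_r$seed <- 10000L + r
    pu <- simulate_pileup(tx, empty, cfg_r)
    nrow(call_editing_sites(pu)) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})
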