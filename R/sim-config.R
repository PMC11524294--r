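#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with validation.  Defaults emulate
#' the study conditions the pipeline targets: a transcriptome of primary
#' transcripts with UTR/CDS/UTR structure; editing events dominated (61\%)
#' by the four types C-to-U, U-to-C, A-to-G and G-to-A; editing degrees
#' averaging ~0.42; coverage comfortably above the 50-read calling floor;
#' 30 expression samples (the library count of the source data); and a
#' purine bias at the -1/+1 flanks of C-to-U sites calibrated so the
#' observed purine fraction is ~0.80.
#'
#' @param n_transcripts number of transcripts.
#' @param utr5_len,cds_len,utr3_len length-2 integer ranges (min, max) in
#'   bp; CDS lengths are drawn as multiples of 3, minimum 6.
#' @param n_sites number of editing events to plant.
#' @param editing_types named non-negative weights over the 12 ordered
#'   substitutions ("A>C", ..., "T>G"); normalized internally.
#' @param degree_range length-2 range of true editing degrees in [0,1].
#' @param coverage_mean mean read coverage (Poisson, truncated at >= 1).
#' @param error_rate per-base sequencing mismatch probability, spread
#'   uniformly over the three non-reference bases.
#' @param motif_prob probability that a planted C-to-U site has its -1 and
#'   +1 flanking bases rewritten to purines (A/G, equal odds).
#' @param n_samples expression samples (>= 5; rank correlation is unstable
#'   below that).
#' @param n_clusters planted coexpression clusters.
#' @param within_cluster_rho target pairwise Spearman correlation inside a
#'   planted cluster.
#' @param ann_n_endo,ann_n_other gene counts of the endosymbiont-derived
#'   and remaining strata for the label-table generator.
#' @param ann_edited_frac_endo,ann_edited_frac_other edited-gene fractions
#'   per stratum (defaults are the study's observed 27.3\% vs 19.5\%).
#' @param ann_n_go_terms,ann_go_term_size GO term count and size range for
#'   the label-table generator.
#' @param seed integer; identical seeds give bit-identical outputs.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_transcripts = 50,
                       utr5_len = c(100L, 300L),
                       cds_len = c(300L, 1500L),
                       utr3_len = c(200L, 600L),
                       n_sites = 200,
                       editing_types = default_editing_weights(),
                       degree_range = c(0.20, 0.64),
                       coverage_mean = 100,
                       error_rate = 0.001,
                       motif_prob = 0.6,
                       n_samples = 30,
                       n_clusters = 6,
                       within_cluster_rho = 0.8,
                       ann_n_endo = 7036,
                       ann_n_other = 35000,
                       ann_edited_frac_endo = 0.273,
                       ann_edited_frac_other = 0.195,
                       ann_n_go_terms = 40,
                       ann_go_term_size = c(10L, 200L),
                       seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    n_sites = as.integer(n_sites),
    editing_types = editing_types,
    degree_range = as.numeric(degree_range),
    coverage_mean = as.numeric(coverage_mean),
    error_rate = as.numeric(error_rate),
    motif_prob = as.numeric(motif_prob),
    n_samples = as.integer(n_samples),
    n_clusters = as.integer(n_clusters),
    within_cluster_rho = as.numeric(within_cluster_rho),
    ann_n_endo = as.integer(ann_n_endo),
    ann_n_other = as.integer(ann_n_other),
    ann_edited_frac_endo = as.numeric(ann_edited_frac_endo),
    ann_edited_frac_other = as.numeric(ann_edited_frac_other),
    ann_n_go_terms = as.integer(ann_n_go_terms),
    ann_go_term_size = as.integer(ann_go_term_size),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

default_editing_weights <- function() {
  w <- setNames(rep(0.387 / 8, 12), EDIT_TYPES)
  w[c("C>T", "T>C", "A>G", "G>A")] <- 0.613 / 4
  w
}

validate_sim_config <- function(cfg) {
  chk_range <- function(r, name, lo = 1L) {
    if (length(r) != 2 || any(r < lo) || r[2] < r[1])
      stop("invalid ", name, " range")
  }
  if (cfg$n_transcripts < 1) stop("n_transcripts must be positive")
  chk_range(cfg$utr5_len, "utr5_len", 0L)
  chk_range(cfg$cds_len, "cds_len", 6L)
  chk_range(cfg$utr3_len, "utr3_len", 0L)
  if (is.null(names(cfg$editing_types)) ||
      !all(names(cfg$editing_types) %in% EDIT_TYPES) ||
      any(cfg$editing_types < 0) || sum(cfg$editing_types) <= 0)
    stop("editing_types must be non-negative weights named by the 12 substitutions")
  probs <- c(cfg$degree_range, cfg$error_rate, cfg$motif_prob,
             cfg$ann_edited_frac_endo, cfg$ann_edited_frac_other)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (cfg$degree_range[2] < cfg$degree_range[1])
    stop("degree_range reversed")
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (cfg$within_cluster_rho < 0 || cfg$within_cluster_rho > 1)
    stop("within_cluster_rho must lie in [0,1]")
  invisible(cfg)
}

# fixed RNG stream offsets, one per generator op
SIM_OFFSETS <- c(transcripts = 101L, sites = 202L, motif = 303L,
                 pileup = 404L, expression = 505L, annotations = 606L)
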