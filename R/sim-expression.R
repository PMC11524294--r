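#' Default gene-role table for the expression simulator
#'
#' Assigns PPR genes and C-to-U target genes to planted clusters, plus
#' optional unclustered background genes.
#'
#' @param config a [sim_config()].
#' @param ppr_per_cluster,targets_per_cluster cluster composition
#'   (>= 1 PPR and >= 3 targets are required downstream).
#' @param n_background unclustered noise genes.
#' @return data.frame with \code{gene_id}, \code{role} ("ppr"/"target"/
#'   "background") and \code{cluster} (NA for background).
#' @export
make_gene_roles <- function(config, ppr_per_cluster = 2,
                            targets_per_cluster = 8, n_background = 0) {
  k <- config$n_clusters
  per <- ppr_per_cluster + targets_per_cluster
  cl <- rep(seq_len(k), each = per)
  role <- rep(c(rep("ppr", ppr_per_cluster),
                rep("target", targets_per_cluster)), k)
  if (n_background > 0) {
    cl <- c(cl, rep(NA_integer_, n_background))
    role <- c(role, rep("background", n_background))
  }
  data.frame(gene_id = sprintf("g%04d", seq_along(cl)),
             role = role, cluster = cl, stringsAsFactors = FALSE)
}

#' Simulate a block-correlated expression matrix
#'
#' Genes in the same planted cluster share a latent per-sample profile so
#' that their pairwise Spearman correlation is \code{within_cluster_rho}
#' in expectation, while between-cluster correlations are centered at 0.
#' Values are log-normal (positive), so they behave like RPKM.
#'
#' The latent model is Gaussian: for a target Spearman rho_s the pairwise
#' correlation of the underlying normals is \code{2*sin(pi*rho_s/6)}
#' (the Spearman/Pearson relation for bivariate normals), obtained by
#' giving every cluster member loading \code{sqrt} of that value on the
#' cluster's latent profile.
#'
#' @param config a [sim_config()]; \code{n_samples} must be >= 5.
#' @param roles optional role table from [make_gene_roles()]; built with
#'   defaults when NULL.
#' @return numeric matrix genes x samples with the role table attached as
#'   attribute \code{"roles"}.
#' @export
simulate_expression <- function(config, roles = NULL) {
  validate_sim_config(config)
  if (config$n_samples < 5)
    stop("n_samples < 5: rank correlation is unstable, refusing")
  if (is.null(roles)) roles <- make_gene_roles(config)
  cl_tab <- table(roles$cluster, roles$role)
  if (config$n_clusters >= 1 && nrow(cl_tab) > 0) {
    if (any(cl_tab[, colnames(cl_tab) == "ppr"] < 1) ||
        any(cl_tab[, colnames(cl_tab) == "target"] < 3))
      stop("every planted cluster needs >= 1 PPR and >= 3 target genes")
  }
  with_op_seed(config$seed, SIM_OFFSETS["expression"], {
    n_g <- nrow(roles); n_s <- config$n_samples
    a <- 2 * sin(pi * config$within_cluster_rho / 6)  # normal-scale corr
    w <- sqrt(a)
    latent <- matrix(rnorm(max(1, config$n_clusters) * n_s), ncol = n_s)
    z <- matrix(rnorm(n_g * n_s), nrow = n_g)
    for (i in seq_len(n_g)) {
      if (!is.na(roles$cluster[i]))
        z[i, ] <- w * latent[roles$cluster[i], ] + sqrt(1 - a) * z[i, ]
    }
    expr <- exp(log(10) + z)   # log-normal around ~10 RPKM
    dimnames(expr) <- list(roles$gene_id,
                           sprintf("s%03d", seq_len(n_s)))
    attr(expr, "roles") <- roles
    expr
  })
}

#' Simulate a gene label table with a planted endosymbiont editing contrast
#'
#' Two strata of genes (endosymbiont-derived and other) are given edited
#' flags at the configured per-stratum fractions, so the planted odds ratio
#' is recoverable by [endosymbiont_fisher()].  GO terms are assigned
#' independently of the edited flag (a true null for enrichment), with
#' term sizes uniform over \code{ann_go_term_size}.
#'
#' @param config a [sim_config()].
#' @return data.frame with \code{gene_id}, \code{go_terms} (semicolon
#'   joined, possibly empty), \code{endosymbiont} and \code{edited} (0/1),
#'   \code{ppr} (all 0; PPR status comes from the expression roles).
#' @export
simulate_annotations <- function(config) {
  validate_sim_config(config)
  with_op_seed(config$seed, SIM_OFFSETS["annotations"], {
    n_e <- config$ann_n_endo; n_o <- config$ann_n_other
    n <- n_e + n_o
    labs <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n)),
      go_terms = "",
      endosymbiont = rep(c(1L, 0L), c(n_e, n_o)),
      ppr = 0L,
      edited = c(rbinom(n_e, 1, config$ann_edited_frac_endo),
                 rbinom(n_o, 1, config$ann_edited_frac_other)),
      stringsAsFactors = FALSE
    )
    sz <- config$ann_go_term_size
    terms <- vector("list", config$ann_n_go_terms)
    assign_lists <- rep(list(character(0)), n)
    for (t in seq_len(config$ann_n_go_terms)) {
      size <- if (sz[1] == sz[2]) sz[1] else sample(seq(sz[1], sz[2]), 1)
      members <- sample(n, min(size, n))
      term <- sprintf("GO:%07d", t)
      for (m in members)
        assign_lists[[m]] <- c(assign_lists[[m]], term)
    }
    labs$go_terms <- vapply(assign_lists, paste, "", collapse = ";")
    labs
  })
}
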