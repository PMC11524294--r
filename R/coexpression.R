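# Shared-Coexpression-Matrix clustering of PPR genes with C-to-U edited
# target genes.  The chain is: editing-degree adjustment of expression ->
# tie-corrected Spearman network -> shared-neighbor counts (the SCM) ->
# greedy seeded decomposition into clusters.

#' Adjust expression by mean editing degree
#'
#' adjusted(g, s) = expr(g, s) * mean_degree(g).  Adjusted expression of
#' an edited gene estimates the abundance of its edited transcripts;
#' unedited genes (PPRs) carry degree 1 and pass through unchanged.
#'
#' @param expr genes x samples matrix (gene rownames).
#' @param degrees named vector of mean editing degrees in [0,1]; genes
#'   absent from it get 1.
#' @return adjusted matrix, same shape.
#' @export
adjust_expression <- function(expr, degrees) {
  if (length(degrees) && (any(degrees < 0) || any(degrees > 1)))
    stop("editing degrees must lie in [0,1]")
  mult <- rep(1, nrow(expr))
  hit <- match(rownames(expr), names(degrees))
  mult[!is.na(hit)] <- degrees[hit[!is.na(hit)]]
  expr * mult
}

#' Spearman coexpression network
#'
#' Pairwise tie-corrected (average-rank) Spearman correlation across
#' samples; an edge joins two genes when rho >= \code{rho_threshold} and
#' the one-sided p-value (t approximation on n-2 df) is <=
#' \code{p_threshold}.  Genes with constant expression have undefined rho
#' and get no edges.
#'
#' @param expr genes x samples matrix (>= 5 samples).
#' @param rho_threshold,p_threshold edge criteria.
#' @return list of class \code{coexpression_network}: \code{rho} matrix,
#'   \code{adjacency} logical matrix (diagonal FALSE), \code{n_samples}.
#' @export
spearman_network <- function(expr, rho_threshold = 0.7, p_threshold = 0.05) {
  ns <- ncol(expr)
  if (ns < 5) stop("need >= 5 samples for a rank-correlation network")
  const <- apply(expr, 1, function(x) length(unique(x)) == 1)
  if (any(const))
    message("spearman_network: ", sum(const),
            " constant genes excluded from edges")
  rho <- suppressWarnings(cor(t(expr), method = "spearman"))
  tstat <- rho * sqrt((ns - 2) / pmax(1e-12, 1 - rho^2))
  pval <- pt(tstat, df = ns - 2, lower.tail = FALSE)
  adj <- rho >= rho_threshold & pval <= p_threshold
  adj[is.na(adj)] <- FALSE
  adj[const, ] <- FALSE; adj[, const] <- FALSE
  diag(adj) <- FALSE
  adj <- adj & t(adj)
  structure(list(rho = rho, adjacency = adj, n_samples = ns),
            class = "coexpression_network")
}

#' Shared Coexpression Matrix
#'
#' scm(i, j) = number of genes coexpressed (adjacent) with both i and j;
#' equivalently the shared-neighbor count, computed as A \%*\% A with a
#' zeroed diagonal.
#'
#' @param network a [spearman_network()] result, or a logical/0-1
#'   symmetric adjacency matrix.
#' @return symmetric integer matrix with zero diagonal.
#' @export
build_scm <- function(network) {
  adj <- if (inherits(network, "coexpression_network"))
    network$adjacency else network
  a <- (adj * 1); diag(a) <- 0
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  scm <- a %*% a
  diag(scm) <- 0
  storage.mode(scm) <- "integer"
  scm
}

#' Significance of a shared-neighbor count
#'
#' Under the null that the neighbor sets of i and j (within the other
#' N = n_genes - 2 genes) are independent uniform draws of their observed
#' sizes, the shared count is Hypergeometric(N, deg_i, deg_j); the
#' one-sided p is P(X >= scm_ij).  Degrees are counted excluding i and j
#' themselves.
#'
#' @param scm_ij observed shared-neighbor count.
#' @param deg_i,deg_j neighbor counts of the two genes (excluding each
#'   other).
#' @param n_genes network size.
#' @return p-value; vectorized.
#' @export
shared_significance <- function(scm_ij, deg_i, deg_j, n_genes) {
  N <- n_genes - 2
  if (any(deg_i > N | deg_j > N)) stop("degree exceeds possible neighbors")
  phyper(scm_ij - 1, m = deg_i, n = N - deg_i, k = deg_j,
         lower.tail = FALSE)
}

# joint-significance p of gene g against current members, on the live network
.pair_p <- function(adj, scm, g, members) {
  n <- nrow(adj)
  vapply(members, function(m) {
    di <- sum(adj[g, ]) - (adj[g, m] * 1)
    dj <- sum(adj[m, ]) - (adj[m, g] * 1)
    shared_significance(scm[g, m], di, dj, n)
  }, 0)
}

#' Greedy decomposition of the SCM into clusters
#'
#' Iteratively: (1) seed with the unassigned pair of largest SCM entry
#' (ties: larger rho, then lexicographic ids); (2) add the third gene with
#' the most significant shared-neighbor overlap with both seeds (each pair
#' p <= \code{p_threshold}); (3) repeatedly add any gene significant with
#' at least three current members; (4) close the cluster and delete its
#' members from the network (deleted genes no longer count as shared
#' neighbors), then repeat.  A seed pair that cannot recruit a third gene
#' is dissolved and masked from future seeding; clusters keep >= 3
#' members by construction.
#'
#' @param network a [spearman_network()] result.
#' @param p_threshold recruitment significance level.
#' @return object of class \code{scm_clusters}: list of clusters, each
#'   with \code{members}, \code{seed} and \code{trace} (join order), plus
#'   an \code{assignment} vector (cluster index or NA per gene).
#' @export
decompose_scm <- function(network, p_threshold = 0.05) {
  ids <- rownames(network$adjacency)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(network$adjacency)))
  live <- rep(TRUE, length(ids))
  masked <- matrix(FALSE, length(ids), length(ids))
  clusters <- list()
  repeat {
    adj <- network$adjacency
    adj[!live, ] <- FALSE; adj[, !live] <- FALSE
    scm <- build_scm(adj)
    cand <- scm
    cand[!live, ] <- -1L; cand[, !live] <- -1L
    cand[masked] <- -1L
    cand[lower.tri(cand, diag = TRUE)] <- -1L
    best <- max(cand)
    if (best <= 0) break
    hits <- which(cand == best, arr.ind = TRUE)
    if (nrow(hits) > 1) {  # tie-break: larger rho, then lexicographic
      rho <- network$rho[hits]
      hits <- hits[order(-rho, ids[hits[, 1]], ids[hits[, 2]]), ,
                   drop = FALSE]
    }
    i <- hits[1, 1]; j <- hits[1, 2]
    # step 2: third gene significant with both seeds
    pool <- which(live); pool <- setdiff(pool, c(i, j))
    p3 <- vapply(pool, function(g) {
      p <- .pair_p(adj, scm, g, c(i, j))
      if (all(p <= p_threshold)) prod(p) else Inf
    }, 0)
    if (length(pool) == 0 || all(is.infinite(p3))) {
      masked[i, j] <- TRUE; masked[j, i] <- TRUE
      next
    }
    ord <- order(p3, ids[pool])
    g3 <- pool[ord[1]]
    members <- c(i, j, g3)
    trace <- ids[members]
    # step 3: recruit genes significant with >= 3 current members
    repeat {
      pool <- setdiff(which(live), members)
      if (length(pool) == 0) break
      score <- vapply(pool, function(g) {
        p <- .pair_p(adj, scm, g, members)
        if (sum(p <= p_threshold) >= 3) min(p) else Inf
      }, 0)
      if (all(is.infinite(score))) break
      nxt <- pool[order(score, ids[pool])[1]]
      members <- c(members, nxt)
      trace <- c(trace, ids[nxt])
    }
    clusters[[length(clusters) + 1]] <-
      list(members = ids[members], seed = ids[c(i, j)], trace = trace)
    live[members] <- FALSE
  }
  assignment <- rep(NA_integer_, length(ids))
  names(assignment) <- ids
  for (ci in seq_along(clusters))
    assignment[clusters[[ci]]$members] <- ci
  structure(list(clusters = clusters, assignment = assignment,
                 p_threshold = p_threshold),
            class = "scm_clusters")
}

#' @export
print.scm_clusters <- function(x, ...) {
  cat("scm_clusters:", length(x$clusters), "clusters,",
      sum(!is.na(x$assignment)), "of", length(x$assignment),
      "genes assigned\n")
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d genes (seed %s-%s)\n", i,
                length(x$clusters[[i]]$members),
                x$clusters[[i]]$seed[1], x$clusters[[i]]$seed[2]))
  invisible(x)
}

#' @export
summary.scm_clusters <- function(object, ...) {
  data.frame(cluster = seq_along(object$clusters),
             size = vapply(object$clusters,
                           function(cl) length(cl$members), 0L))
}

#' Per-cluster composition report
#'
#' Counts PPR genes and edited target genes per cluster (the two columns
#' of the study's cluster table) with totals; optionally the
#' organelle-targeted fraction when the label table carries an
#' \code{organelle} flag.
#'
#' @param clusters an \code{scm_clusters} object, or a data.frame with
#'   \code{cluster} and \code{gene_id}.
#' @param labels data.frame with \code{gene_id}, \code{ppr} (0/1),
#'   \code{edited} (0/1) and optionally \code{organelle} (0/1).
#' @return data.frame: cluster, n_edited_genes, n_ppr (and
#'   organelle_fraction when available), with a final "total" row.
#' @export
cluster_report <- function(clusters, labels) {
  memb <- if (inherits(clusters, "scm_clusters")) {
    do.call(rbind, lapply(seq_along(clusters$clusters), function(i)
      data.frame(cluster = i, gene_id = clusters$clusters[[i]]$members,
                 stringsAsFactors = FALSE)))
  } else as.data.frame(clusters)
  if (is.null(memb) || nrow(memb) == 0)
    return(data.frame(cluster = character(), n_edited_genes = integer(),
                      n_ppr = integer()))
  li <- match(memb$gene_id, labels$gene_id)
  memb$ppr <- labels$ppr[li] == 1
  memb$edited <- labels$edited[li] == 1
  per <- do.call(rbind, lapply(split(memb, memb$cluster), function(d)
    data.frame(cluster = as.character(d$cluster[1]),
               n_edited_genes = sum(d$edited & !d$ppr, na.rm = TRUE),
               n_ppr = sum(d$ppr, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  if ("organelle" %in% names(labels)) {
    per$organelle_fraction <- vapply(split(memb, memb$cluster), function(d) {
      ed <- d$edited & !d$ppr
      if (!any(ed, na.rm = TRUE)) return(NA_real_)
      mean(labels$organelle[match(d$gene_id[ed], labels$gene_id)] == 1,
           na.rm = TRUE)
    }, 0)
  }
  total <- per[1, , drop = FALSE]
  total$cluster <- "total"
  total$n_edited_genes <- sum(per$n_edited_genes)
  total$n_ppr <- sum(per$n_ppr)
  if ("organelle_fraction" %in% names(per))
    total$organelle_fraction <- NA_real_
  out <- rbind(per, total)
  rownames(out) <- NULL
  out
}
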