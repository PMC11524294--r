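# Enrichment statistics: hypergeometric GO over-representation of edited
# genes and Fisher's exact test for editing enrichment among
# endosymbiont-derived genes.  All tests are one-sided (greater): every
# claim tested is an over-representation claim.

#' Upper hypergeometric tail
#'
#' P(X >= k) with X ~ Hypergeometric(N, K, n): k edited genes observed in
#' a term of size K, with n edited genes in a universe of N.
#'
#' @param k observed overlap.
#' @param K term (category) size.
#' @param n number of edited genes.
#' @param N universe size.
#' @return p-value in (0,1]; vectorized.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)))
    stop("inconsistent hypergeometric counts")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

# explode a label table into term -> gene-index list
split_terms <- function(go_terms) {
  lst <- strsplit(go_terms, ";", fixed = TRUE)
  gene <- rep(seq_along(lst), lengths(lst))
  term <- unlist(lst, use.names = FALSE)
  keep <- !is.na(term) & nzchar(term)
  split(gene[keep], term[keep])
}

#' GO-term enrichment of edited genes
#'
#' One upper-tail hypergeometric test per term present on at least one
#' gene of the universe (the supplied label table defines the universe).
#' Raw p-values are filtered at \code{alpha} (no multiple-testing
#' correction by default, \code{fdr = TRUE} adds BH) and rows are sorted
#' by p.  Edited and non-edited percentages per term are reported.
#'
#' @param labels label table with \code{gene_id}, \code{go_terms}
#'   (semicolon-joined) and \code{edited} (0/1).
#' @param alpha significance cut on the (possibly adjusted) p-value.
#' @param fdr apply BH across terms before filtering.
#' @return data.frame: term, k (edited in term), K (term size), n, N,
#'   p_value, edited_pct, nonedited_pct.
#' @export
go_enrichment <- function(labels, alpha = 0.05, fdr = FALSE) {
  stopifnot(nrow(labels) > 0)
  terms <- split_terms(labels$go_terms)
  N <- nrow(labels)
  n <- sum(labels$edited == 1)
  rows <- data.frame(
    term = names(terms),
    k = vapply(terms, function(g) sum(labels$edited[g] == 1), 0L),
    K = lengths(terms),
    n = n, N = N, row.names = NULL, stringsAsFactors = FALSE
  )
  rows$p_value <- hypergeom_tail(rows$k, rows$K, rows$n, rows$N)
  if (fdr) rows$p_value <- adjust_fdr(rows$p_value)
  rows$edited_pct <- 100 * rows$k / rows$K
  rows$nonedited_pct <- 100 - rows$edited_pct
  rows <- rows[rows$p_value < alpha, , drop = FALSE]
  rows[order(rows$p_value), , drop = FALSE]
}

#' Editing enrichment among endosymbiont-derived genes
#'
#' Builds the 2x2 table edited/non-edited x endosymbiont/other and tests
#' over-representation of editing in the endosymbiont stratum with a
#' one-sided Fisher's exact test.
#'
#' @param labels label table with \code{gene_id}, \code{endosymbiont} and
#'   \code{edited} flags.
#' @return list: \code{table} (2x2), \code{odds_ratio} (conditional MLE),
#'   \code{p_value}, \code{fraction_endo}, \code{fraction_other}.
#' @export
endosymbiont_fisher <- function(labels) {
  endo <- labels$endosymbiont == 1
  ed <- labels$edited == 1
  if (!any(endo) || !any(!endo)) stop("both strata must be nonempty")
  tab <- matrix(c(sum(ed & endo), sum(!ed & endo),
                  sum(ed & !endo), sum(!ed & !endo)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("endosymbiont", "other"),
                                c("edited", "non_edited")))
  ft <- fisher.test(tab, alternative = "greater")
  list(table = tab,
       odds_ratio = unname(ft$estimate),
       p_value = ft$p.value,
       fraction_endo = tab[1, 1] / sum(tab[1, ]),
       fraction_other = tab[2, 1] / sum(tab[2, ]))
}
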