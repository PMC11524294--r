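# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately avoid the code paths they check.

# upper hypergeometric tail P(X >= k) by direct enumeration with choose()
enum_hyper_tail <- function(k, K, n, N) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  if (k > hi) return(0)
  xs <- max(k, lo):hi
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# one-sided (greater) Fisher exact p for table [[a, b], [c, d]] by
# enumerating the hypergeometric support of the (1,1) cell
enum_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; tot <- a + b + c + d
  lo <- max(0, c1 - (tot - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(r1, xs) * choose(tot - r1, c1 - xs) / choose(tot, c1)
  sum(probs[xs >= a])
}

# shared-neighbor count matrix by explicit set intersection
brute_scm <- function(adj) {
  n <- nrow(adj)
  out <- matrix(0L, n, n, dimnames = dimnames(adj))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out[i, j] <- length(intersect(setdiff(which(adj[i, ]), c(i, j)),
                                  setdiff(which(adj[j, ]), c(i, j))))
  }
  out
}

# adjusted Rand index from two label vectors (NA = unassigned, kept as
# its own label per element)
ari <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  a[is.na(a)] <- paste0(".na", seq_along(a))[is.na(a)]
  b[is.na(b)] <- paste0(".nb", seq_along(b))[is.na(b)]
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- si * sj / np
  (sij - expected) / ((si + sj) / 2 - expected)
}

# a tiny deterministic transcript set for unit tests: 10 nt 5'UTR,
# 12 nt CDS (ATG ... stop), 8 nt 3'UTR
tiny_transcripts <- function() {
  transcript_set(
    id = c("t1", "t2"),
    sequence = c(
      paste0("AACCGGTTAC", "ATGGCCCATCGA", "TAAGGCCA"),
      paste0("GGGGGTTTTC", "ATGCGACACTGA", "CCCCAAAA")
    ),
    cds_start = c(10L, 10L), cds_end = c(22L, 22L)
  )
}

# point-mass editing weights on one substitution
point_weights <- function(type) {
  w <- setNames(numeric(12), nucredit:::EDIT_TYPES)
  w[type] <- 1
  w
}
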