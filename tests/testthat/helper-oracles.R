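# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# Minimal number of present->absent transitions on a rooted tree under a
# single-gain irreversible-loss model, by exhaustive enumeration of all
# internal-state assignments. The root subtends a pseudo-branch from a
# present ancestor, so a root scored absent costs one stem loss (when
# ancestral presence is assumed).
dolloOracle <- function(tree, states, assumeRootPresent = TRUE) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tipState <- as.integer(states[tree$tip.label])
  edges <- tree$edge
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(mask)[seq_len(nnode)])
    full <- c(tipState, internal)
    root <- full[ntip + 1L]
    # no gains anywhere (0 -> 1 along an edge is forbidden)
    if (any(full[edges[, 1]] == 0L & full[edges[, 2]] == 1L)) next
    cost <- sum(full[edges[, 1]] == 1L & full[edges[, 2]] == 0L)
    if (assumeRootPresent && root == 0L) cost <- cost + 1L
    if (!assumeRootPresent && root == 0L && any(tipState == 1L)) next
    best <- min(best, cost)
  }
  as.integer(best)
}

# Best colinear chain by enumeration of all hit subsets, using the same
# pairwise compatibility rule as the chainer but none of its DP machinery.
chainOracleScore <- function(hits, maxOverlap = 9L) {
  n <- nrow(hits)
  if (n == 0L) return(0)
  compat <- function(j, i) {
    hj <- hits[j, ]; hi <- hits[i, ]
    hj$gStart < hi$gStart && hj$gEnd < hi$gEnd &&
      hj$gEnd - hi$gStart <= maxOverlap &&
      hj$pStart < hi$pStart && hj$pEnd < hi$pEnd &&
      hj$pEnd - hi$pStart <= ceiling(maxOverlap / 3)
  }
  best <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(as.logical(intToBits(mask)[seq_len(n)]))
    idx <- idx[order(hits$gStart[idx], hits$pStart[idx])]
    ok <- TRUE
    if (length(idx) > 1L) {
      for (q in 2:length(idx)) {
        if (!compat(idx[q - 1L], idx[q])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(hits$score[idx]))
  }
  best
}

# random binary vector guaranteed non-constant
randomNonConstant <- function(n) {
  repeat {
    v <- sample(0:1, n, replace = TRUE)
    if (length(unique(v)) > 1L) return(v)
  }
}

# random reference protein over the 20 standard residues
randomProtein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# reference positions covered by a set of protein intervals
coveredPositions <- function(df) {
  if (!nrow(df)) return(integer(0))
  unlist(lapply(seq_len(nrow(df)), function(i)
    seq(df$pStart[i], df$pEnd[i] - 1L)))
}
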