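## Correlation of paired binary loss-event vectors with permutation nulls.
##
## The statistic is Pearson's product-moment correlation of two 0/1
## vectors, i.e. the 2x2 phi coefficient. The null distribution is formed
## by margin-preserving random permutation of one vector (conditioning on
## the observed number of loss events), with an exhaustive enumeration
## oracle for small n and an optional i.i.d. Bernoulli resampling mode.

#' Phi coefficient (Pearson r) of two binary vectors
#'
#' Computes Pearson's product-moment correlation of two equal-length 0/1
#' vectors, which equals the 2x2-contingency phi coefficient
#' \eqn{(n_{11} n_{00} - n_{10} n_{01}) / \sqrt{n_{1.} n_{0.} n_{.1} n_{.0}}}.
#'
#' @param x,y binary vectors of equal length \eqn{\ge} 2, neither constant.
#' @return The correlation, a number in [-1, 1].
#' @examples
#' phiCorrelation(c(1, 1, 0, 0), c(0, 0, 1, 1))  # -1
#' @export
phiCorrelation <- function(x, y) {
  x <- assertBinaryVector(x, "x")
  y <- assertBinaryVector(y, "y")
  n <- length(x)
  if (n < 2L || length(y) != n)
    stop("'x' and 'y' must have equal length >= 2")
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 || sx == n)
    stop("correlation undefined: 'x' is constant")
  if (sy == 0 || sy == n)
    stop("correlation undefined: 'y' is constant")
  n11 <- sum(x == 1 & y == 1)
  (n * n11 - sx * sy) / sqrt(sx * (n - sx) * sy * (n - sy))
}

tailMatch <- function(tail) match.arg(tail, c("two_sided", "greater"))

#' Permutation test for association of two binary loss vectors
#'
#' Compares the observed phi coefficient against its distribution under
#' random permutation of \code{y} (method \code{"shuffle"}, the default:
#' margin-preserving, conditioning on the observed number of events). For
#' a uniformly random permutation the statistic depends on the permuted
#' vector only through the overlap count \eqn{n_{11}}, which follows a
#' hypergeometric law at fixed margins; draws are therefore taken directly
#' from that law and extremeness is decided in exact integer arithmetic
#' (phi is monotone-linear in \eqn{n_{11}}). Method \code{"bernoulli"}
#' instead resamples \code{y} i.i.d. Bernoulli with its empirical rate
#' (margins free to vary); resamples with a constant vector have an
#' undefined statistic and are counted as not extreme.
#'
#' The empirical p-value uses the add-one correction
#' \eqn{p = (1 + \#\{\mathrm{as\ extreme}\}) / (n_{\mathrm{perm}} + 1)},
#' so it is never exactly zero.
#'
#' @param x,y binary vectors, neither constant.
#' @param nPerm number of permutations (default 500000).
#' @param seed mandatory integer seed; results are reproducible given it.
#' @param tail \code{"two_sided"} (on |r|, default) or \code{"greater"}.
#' @param method \code{"shuffle"} or \code{"bernoulli"}.
#' @param pair optional character(2) label for the result.
#' @return A \code{\linkS4class{CoevolutionResult}}.
#' @examples
#' permutationTest(c(1, 1, 0, 0), c(1, 1, 0, 0), nPerm = 1000, seed = 1)
#' @export
permutationTest <- function(x, y, nPerm = 500000L, seed,
                            tail = c("two_sided", "greater"),
                            method = c("shuffle", "bernoulli"),
                            pair = character(0)) {
  tail <- tailMatch(tail)
  method <- match.arg(method)
  if (missing(seed)) stop("'seed' is required for reproducibility")
  nPerm <- as.integer(nPerm)
  if (is.na(nPerm) || nPerm < 1L) stop("'nPerm' must be a positive integer")
  robs <- phiCorrelation(x, y)          # also validates inputs
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); sx <- sum(x); sy <- sum(y)
  n11obs <- sum(x == 1 & y == 1)

  nExtreme <- withSeed(seed, {
    if (method == "shuffle") {
      # T(n11) = n*n11 - sx*sy is an integer, linear in n11 at fixed margins
      n11 <- rhyper(nPerm, m = sx, n = n - sx, k = sy)
      Tobs <- n * n11obs - sx * sy
      Tp <- n * n11 - sx * sy
      if (tail == "two_sided") sum(abs(Tp) >= abs(Tobs)) else sum(Tp >= Tobs)
    } else {
      syp <- rbinom(nPerm, n, sy / n)
      ok <- syp > 0 & syp < n
      n11 <- integer(nPerm)
      n11[ok] <- rhyper(sum(ok), m = sx, n = n - sx, k = syp[ok])
      rp <- rep(NA_real_, nPerm)
      rp[ok] <- (n * n11[ok] - sx * syp[ok]) /
        sqrt(sx * (n - sx) * syp[ok] * (n - syp[ok]))
      if (tail == "two_sided") sum(abs(rp) >= abs(robs) - 1e-12, na.rm = TRUE)
      else sum(rp >= robs - 1e-12, na.rm = TRUE)
    }
  })
  new("CoevolutionResult", pair = pair, rObserved = robs,
      pEmpirical = (1 + nExtreme) / (nPerm + 1),
      nPermutations = nPerm, seed = as.integer(seed), tail = tail,
      note = method)
}

#' Exact permutation p-value by exhaustive enumeration (small n)
#'
#' Enumerates every distinct arrangement of \code{y} (all position subsets
#' for its ones — arrangements are equiprobable under uniform permutation)
#' and returns the exact tail probability of the phi statistic, without
#' the add-one correction. Serves as the independent oracle for
#' \code{\link{permutationTest}}; it recomputes phi through
#' \code{\link{phiCorrelation}} for every arrangement rather than using
#' any distributional shortcut.
#'
#' @param x,y binary vectors of length \eqn{\le} 10, neither constant.
#' @param tail \code{"two_sided"} or \code{"greater"}.
#' @return Exact p-value in (0, 1].
#' @examples
#' exhaustivePermutationP(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1/3
#' @export
exhaustivePermutationP <- function(x, y, tail = c("two_sided", "greater")) {
  tail <- tailMatch(tail)
  robs <- phiCorrelation(x, y)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n > 10L)
    stop("n > 10: use the Monte-Carlo permutationTest instead")
  sy <- sum(y)
  subsets <- combn(n, sy)
  hits <- 0L
  for (j in seq_len(ncol(subsets))) {
    yp <- numeric(n)
    yp[subsets[, j]] <- 1
    rp <- phiCorrelation(x, yp)
    ex <- if (tail == "two_sided") abs(rp) >= abs(robs) - 1e-12
          else rp >= robs - 1e-12
    if (ex) hits <- hits + 1L
  }
  hits / ncol(subsets)
}

#' Pairwise coevolution tests over a loss-event table
#'
#' Runs \code{\link{permutationTest}} for every unordered pair of gene
#' columns of a \code{\linkS4class{LossEventTable}}. A pair involving a
#' column that is constant across rows is reported as undefined (with a
#' diagnostic note) while the remaining pairs are still computed. Each
#' pair uses a distinct seed derived deterministically from \code{seed}.
#'
#' @param table a \code{\linkS4class{LossEventTable}} or 0/1 matrix with
#'   \eqn{\ge} 2 rows and \eqn{\ge} 2 gene columns.
#' @param nPerm,seed,tail,method passed to \code{\link{permutationTest}}.
#' @return Named list of \code{\linkS4class{CoevolutionResult}} objects,
#'   one per unordered pair, named \code{"geneA:geneB"}.
#' @export
pairwiseCoevolution <- function(table, nPerm = 500000L, seed,
                                tail = c("two_sided", "greater"),
                                method = c("shuffle", "bernoulli")) {
  tail <- tailMatch(tail)
  method <- match.arg(method)
  if (missing(seed)) stop("'seed' is required for reproducibility")
  ev <- if (is(table, "LossEventTable")) eventMatrix(table) else table
  if (!is.matrix(ev) || nrow(ev) < 2L || ncol(ev) < 2L)
    stop("'table' must have at least 2 rows and 2 gene columns")
  genes <- colnames(ev)
  prs <- combn(genes, 2L)
  out <- vector("list", ncol(prs))
  names(out) <- apply(prs, 2L, paste, collapse = ":")
  for (j in seq_len(ncol(prs))) {
    g1 <- prs[1L, j]; g2 <- prs[2L, j]
    x <- ev[, g1]; y <- ev[, g2]
    const <- c(g1, g2)[c(length(unique(x)) == 1L, length(unique(y)) == 1L)]
    if (length(const)) {
      out[[j]] <- new("CoevolutionResult", pair = c(g1, g2),
                      rObserved = NA_real_, pEmpirical = NA_real_,
                      nPermutations = 0L, seed = as.integer(seed),
                      tail = tail,
                      note = paste("undefined: constant loss column for",
                                   paste(const, collapse = ", ")))
    } else {
      out[[j]] <- permutationTest(x, y, nPerm = nPerm,
                                  seed = as.integer(seed) + j,
                                  tail = tail, method = method,
                                  pair = c(g1, g2))
    }
  }
  out
}
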