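## Protein-alignment utilities: site-coverage trimming and per-column
## conservation labelling. Alignments themselves are inputs (e.g. aligned
## FASTA from ClustalW/MAFFT); they are never computed here.

GAP_CHARS <- c("-", ".")

# fixed amino-acid similarity classes used for the "similar" call;
# declared here once and reported in output metadata
SIMILARITY_GROUPS <- list(
  aliphatic = c("A", "V", "L", "I", "M"),
  aromatic = c("F", "W", "Y"),
  hydroxyl = c("S", "T"),
  acidic = c("D", "E"),
  basic = c("K", "R", "H"),
  amide = c("N", "Q"),
  small_turn = c("G", "P"),
  cysteine = c("C")
)

alignmentToMatrix <- function(alignment) {
  if (is(alignment, "AAMultipleAlignment"))
    alignment <- Biostrings::unmasked(alignment)
  if (is(alignment, "AAStringSet") || is(alignment, "BStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  if (is.matrix(alignment)) return(alignment)
  if (!is.character(alignment) || length(alignment) < 2L)
    stop("alignment must have at least 2 rows")
  w <- unique(nchar(alignment))
  if (length(w) != 1L)
    stop("alignment rows must all have the same length")
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

matrixToAlignment <- function(m, template) {
  rows <- apply(m, 1L, paste, collapse = "")
  if (length(rows) == 0L) rows <- setNames(character(0), character(0))
  if (is(template, "AAStringSet") || is(template, "AAMultipleAlignment"))
    return(Biostrings::AAStringSet(rows))
  rows
}

#' Trim alignment columns with low site coverage
#'
#' Removes every column whose non-gap fraction (site coverage) is
#' strictly below \code{minCoverage}; a column at exactly the threshold
#' is kept. Column order is otherwise preserved and row names are kept.
#' The operation is idempotent.
#'
#' @param alignment a protein alignment: named character vector of
#'   equal-length gapped rows, \code{AAStringSet}, or character matrix
#'   (one residue per cell). Gap characters are \code{"-"} and \code{"."}.
#' @param minCoverage minimum non-gap fraction per column (default 0.8).
#' @return The trimmed alignment, same representation as the input. If no
#'   column survives, an empty alignment is returned with a warning.
#' @examples
#' aln <- c(a = "MK-V", b = "MKLV", c = "MKLV", d = "MKLV")
#' trimLowCoverageColumns(aln, 0.8)  # column 3 (coverage 3/4 < 0.8) removed
#' @export
trimLowCoverageColumns <- function(alignment, minCoverage = 0.8) {
  m <- alignmentToMatrix(alignment)
  cov <- colMeans(!apply(m, 2L, `%in%`, GAP_CHARS))
  keep <- cov >= minCoverage
  if (!any(keep)) {
    warning("no column reaches the coverage threshold; ",
            "returning an empty alignment")
  }
  matrixToAlignment(m[, keep, drop = FALSE], alignment)
}

#' Label alignment columns as conserved, similar or neither
#'
#' A column is \code{"conserved"} when a single residue occupies at least
#' \code{threshold} of its non-gap entries; failing that it is
#' \code{"similar"} when a single amino-acid similarity class does (the
#' fixed classes AVLIM / FWY / ST / DE / KRH / NQ / GP / C); otherwise
#' \code{"none"}. Columns with no non-gap entries are \code{"none"}.
#'
#' @param alignment protein alignment (see
#'   \code{\link{trimLowCoverageColumns}}).
#' @param threshold minimum fraction (default 0.5).
#' @return Character vector of per-column labels, with the similarity
#'   classes attached as attribute \code{"groups"}.
#' @examples
#' columnConservation(c(a = "AI", b = "AL", c = "AV", d = "AM"))
#' # "conserved" "similar"
#' @export
columnConservation <- function(alignment, threshold = 0.5) {
  m <- alignmentToMatrix(alignment)
  grp <- setNames(rep(names(SIMILARITY_GROUPS), lengths(SIMILARITY_GROUPS)),
                  unlist(SIMILARITY_GROUPS, use.names = FALSE))
  labelOne <- function(col) {
    res <- col[!(col %in% GAP_CHARS)]
    if (!length(res)) return("none")
    if (max(table(res)) / length(res) >= threshold) return("conserved")
    g <- grp[res]
    if (any(!is.na(g)) &&
        max(table(g[!is.na(g)])) / length(res) >= threshold)
      return("similar")
    "none"
  }
  out <- apply(m, 2L, labelOne)
  attr(out, "groups") <- SIMILARITY_GROUPS
  out
}
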