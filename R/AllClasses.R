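#' @import methods
#' @importFrom stats rbinom rhyper runif setNames
#' @importFrom utils combn head
NULL

#' Gene statuses and pattern codes
#'
#' Per-species gene status takes one of four values: \code{"present"} (an
#' intact orthologue satisfying the domain rules), \code{"homologue_only"}
#' (a related protein missing a diagnostic feature, e.g. an NHE with a CNBD
#' but no voltage-sensor domain), \code{"pseudogene"} (a degraded remnant
#' identified by curation or remnant scanning), and \code{"absent"}.
#' Only \code{"present"} counts as presence when statuses are collapsed to
#' binary for pattern codes and loss inference.
#'
#' @name gene-status
#' @keywords internal
NULL

GENE_STATUSES <- c("present", "homologue_only", "pseudogene", "absent")
PATTERN_CODES <- c("All", "None", "Int1", "Int2", "Int3", "Other")
CORE_GENES <- c("CatSper", "sNHE", "sAC")

#' DomainRecord: one sequence's annotated domain architecture
#'
#' Container for the domain content of a single predicted protein in one
#' species: the diagnostic domain tokens, the transmembrane-segment count,
#' and a coarse gene-family hint used to route the record to the right
#' classification rule.
#'
#' @slot species single species name.
#' @slot sequenceId sequence identifier, unique within a species' records.
#' @slot familyHint one of \code{"catsper_alpha"}, \code{"catsper_auxiliary"},
#'   \code{"nhe"}, \code{"ac"}, \code{"other"}.
#' @slot domains character vector of domain tokens from the controlled
#'   vocabulary (see \code{\link{normalizeDomainTokens}}); unrecognised
#'   tokens are kept but flagged.
#' @slot tmCount non-negative integer count of transmembrane segments.
#' @slot pseudogene logical; \code{TRUE} marks a curated pseudogenic record,
#'   which never counts as intact.
#'
#' @seealso \code{\link{classifyCatSper}}, \code{\link{classifySlc9c}},
#'   \code{\link{classifySac}}
#' @export
setClass("DomainRecord",
  representation(
    species = "character",
    sequenceId = "character",
    familyHint = "character",
    domains = "character",
    tmCount = "integer",
    pseudogene = "logical"
  ),
  prototype(domains = character(0), tmCount = 0L, pseudogene = FALSE)
)

setValidity("DomainRecord", function(object) {
  msgs <- character(0)
  if (length(object@species) != 1L || !nzchar(object@species))
    msgs <- c(msgs, "species must be a single non-empty string")
  if (length(object@sequenceId) != 1L || !nzchar(object@sequenceId))
    msgs <- c(msgs, "sequenceId must be a single non-empty string")
  hints <- c("catsper_alpha", "catsper_auxiliary", "nhe", "ac", "other")
  if (length(object@familyHint) != 1L || !(object@familyHint %in% hints))
    msgs <- c(msgs, paste0("familyHint must be one of: ",
                           paste(hints, collapse = ", ")))
  if (length(object@tmCount) != 1L || is.na(object@tmCount) ||
      object@tmCount < 0L)
    msgs <- c(msgs, "tmCount must be a single non-negative integer")
  if (length(object@pseudogene) != 1L || is.na(object@pseudogene))
    msgs <- c(msgs, "pseudogene must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DomainRecord
#'
#' @param species,sequenceId single strings.
#' @param familyHint gene-family routing hint.
#' @param domains character vector of domain tokens; normalised against the
#'   controlled vocabulary.
#' @param tmCount transmembrane-segment count.
#' @param pseudogene logical pseudogene flag.
#' @return A \code{\linkS4class{DomainRecord}}.
#' @examples
#' DomainRecord("Homo_sapiens", "sNHE_1", "nhe",
#'              c("NHE_exchanger", "VSD", "CNBD"), tmCount = 13)
#' @export
DomainRecord <- function(species, sequenceId, familyHint,
                         domains = character(0), tmCount = 0L,
                         pseudogene = FALSE) {
  new("DomainRecord",
      species = as.character(species),
      sequenceId = as.character(sequenceId),
      familyHint = as.character(familyHint),
      domains = normalizeDomainTokens(as.character(domains)),
      tmCount = as.integer(tmCount),
      pseudogene = isTRUE(pseudogene))
}

setMethod("show", "DomainRecord", function(object) {
  cat("DomainRecord:", object@sequenceId, "(", object@species, ")\n",
      " family:", object@familyHint,
      " tm:", object@tmCount,
      if (object@pseudogene) " [pseudogene]" else "", "\n",
      " domains:", if (length(object@domains))
        paste(object@domains, collapse = ", ") else "(none)", "\n")
})

#' LossEventTable: binary table of per-branch gene-loss events
#'
#' Rows are tree branches (identified by the branch's child node, see
#' \code{\link{branchIds}}) on which at least one gene was lost under the
#' fewest-event reconstruction; columns are genes; entries are 0/1. This is
#' the "binary code" input to the coevolution statistics.
#'
#' @slot events integer 0/1 matrix with branch row names and gene column
#'   names. Every row has at least one 1.
#'
#' @seealso \code{\link{buildEventTable}}, \code{\link{pairwiseCoevolution}}
#' @export
setClass("LossEventTable", representation(events = "matrix"))

setValidity("LossEventTable", function(object) {
  ev <- object@events
  msgs <- character(0)
  if (!is.numeric(ev))
    msgs <- c(msgs, "events must be a numeric matrix")
  else {
    if (length(ev) && !all(ev %in% c(0, 1)))
      msgs <- c(msgs, "entries must be 0 or 1")
    if (nrow(ev) > 0 && any(rowSums(ev) < 1))
      msgs <- c(msgs, "every row must record at least one loss")
    if (is.null(colnames(ev)) || anyDuplicated(colnames(ev)))
      msgs <- c(msgs, "columns must carry unique gene names")
    if (nrow(ev) > 0 && (is.null(rownames(ev)) || anyDuplicated(rownames(ev))))
      msgs <- c(msgs, "rows must carry unique branch ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a LossEventTable from a 0/1 matrix
#'
#' @param events 0/1 matrix, rows = branches, columns = genes.
#' @return A \code{\linkS4class{LossEventTable}}.
#' @export
LossEventTable <- function(events) {
  storage.mode(events) <- "integer"
  new("LossEventTable", events = events)
}

#' @describeIn LossEventTable-class the underlying 0/1 matrix.
#' @param x a \code{LossEventTable}.
#' @export
eventMatrix <- function(x) {
  stopifnot(is(x, "LossEventTable"))
  x@events
}

#' @describeIn LossEventTable-class branch (row) identifiers.
#' @export
eventBranches <- function(x) rownames(eventMatrix(x))

#' @describeIn LossEventTable-class gene (column) names.
#' @export
eventGenes <- function(x) colnames(eventMatrix(x))

setMethod("show", "LossEventTable", function(object) {
  ev <- object@events
  cat("LossEventTable:", nrow(ev), "branch(es) x", ncol(ev), "gene(s)\n")
  if (nrow(ev)) {
    cat(" per-gene loss counts:",
        paste(colnames(ev), colSums(ev), sep = "=", collapse = ", "), "\n")
    print(head(ev, 8))
    if (nrow(ev) > 8) cat(" ...", nrow(ev) - 8, "more row(s)\n")
  }
})

setMethod("dim", "LossEventTable", function(x) dim(x@events))

#' CoevolutionResult: correlation of two binary loss vectors with its
#' permutation p-value
#'
#' @slot pair the two variable (gene) names, or empty for anonymous vectors.
#' @slot rObserved observed phi coefficient (Pearson r of the 0/1 vectors);
#'   \code{NA} when undefined (a constant vector).
#' @slot pEmpirical add-one-corrected empirical p-value in (0, 1].
#' @slot nPermutations number of Monte-Carlo permutations.
#' @slot seed RNG seed used.
#' @slot tail \code{"two_sided"} (on |r|) or \code{"greater"}.
#' @slot note diagnostic note, e.g. why a result is undefined.
#' @export
setClass("CoevolutionResult",
  representation(
    pair = "character",
    rObserved = "numeric",
    pEmpirical = "numeric",
    nPermutations = "integer",
    seed = "integer",
    tail = "character",
    note = "character"
  ),
  prototype(pair = character(0), note = "")
)

setValidity("CoevolutionResult", function(object) {
  msgs <- character(0)
  if (!is.na(object@rObserved) && abs(object@rObserved) > 1 + 1e-12)
    msgs <- c(msgs, "|rObserved| must be <= 1")
  if (!is.na(object@pEmpirical)) {
    if (object@pEmpirical <= 0 || object@pEmpirical > 1)
      msgs <- c(msgs, "pEmpirical must lie in (0, 1]")
    if (object@nPermutations >= 1L &&
        object@pEmpirical < 1 / (object@nPermutations + 1) - 1e-15)
      msgs <- c(msgs, "pEmpirical must be >= 1/(nPermutations + 1)")
  }
  if (!(object@tail %in% c("two_sided", "greater")))
    msgs <- c(msgs, "tail must be 'two_sided' or 'greater'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CoevolutionResult", function(object) {
  lbl <- if (length(object@pair) == 2L)
    paste(object@pair, collapse = " ~ ") else "x ~ y"
  cat("CoevolutionResult:", lbl, "\n")
  if (is.na(object@rObserved)) {
    cat(" undefined:", object@note, "\n")
  } else {
    cat(sprintf(" r = %.4f, p = %.3g (%s, %d permutations, seed %d)\n",
                object@rObserved, object@pEmpirical, object@tail,
                object@nPermutations, object@seed))
  }
})

#' RemnantChain: colinear chained remnant hits against a reference protein
#'
#' An ordered set of translated genomic segments (exon-like remnant hits)
#' that is strictly colinear in both genomic and protein coordinates,
#' selected to maximise total alignment score.
#'
#' @slot hits data.frame of hits in chain order, with columns
#'   \code{frame}, \code{gStart}, \code{gEnd} (0-based half-open,
#'   forward strand), \code{pStart}, \code{pEnd} (0-based half-open on the
#'   reference protein), \code{score}, \code{pident}, \code{segment}
#'   (the translated genomic residues that aligned).
#' @slot totalScore summed (overlap-trimmed) score of the chained hits.
#' @slot referenceCoverage fraction of reference positions covered by the
#'   chain's protein intervals; \code{NA} if the reference length is unknown.
#' @export
setClass("RemnantChain",
  representation(
    hits = "data.frame",
    totalScore = "numeric",
    referenceCoverage = "numeric"
  ),
  prototype(totalScore = 0, referenceCoverage = NA_real_)
)

setValidity("RemnantChain", function(object) {
  h <- object@hits
  if (nrow(h) < 2L) return(TRUE)
  ok_g <- all(diff(h$gStart) > 0) && all(h$gEnd[-nrow(h)] <= h$gStart[-1])
  ok_p <- all(diff(h$pStart) > 0) && all(h$pEnd[-nrow(h)] <= h$pStart[-1])
  if (!ok_g) return("hits must be strictly colinear and disjoint in genomic coordinates")
  if (!ok_p) return("hits must be strictly colinear and non-overlapping in protein coordinates")
  TRUE
})

setMethod("show", "RemnantChain", function(object) {
  cat("RemnantChain:", nrow(object@hits), "hit(s), total score",
      round(object@totalScore, 1), "\n")
  if (!is.na(object@referenceCoverage))
    cat(sprintf(" reference coverage: %.1f%%\n",
                100 * object@referenceCoverage))
  if (nrow(object@hits))
    print(object@hits[, c("frame", "gStart", "gEnd", "pStart", "pEnd",
                          "score", "pident")])
})

#' @describeIn RemnantChain-class the chained hits in order.
#' @param x a \code{RemnantChain}.
#' @export
chainHits <- function(x) {
  stopifnot(is(x, "RemnantChain"))
  x@hits
}

#' @describeIn RemnantChain-class total chained score.
#' @export
chainScore <- function(x) {
  stopifnot(is(x, "RemnantChain"))
  x@totalScore
}

#' @describeIn RemnantChain-class fraction of the reference covered.
#' @export
referenceCoverage <- function(x) {
  stopifnot(is(x, "RemnantChain"))
  x@referenceCoverage
}

#' CuratedFixture: packaged species tree plus curated gene-status records
#'
#' @slot name fixture name.
#' @slot tree rooted \code{ape::phylo} species tree (topology only).
#' @slot records data.frame with columns \code{species}, \code{taxon_group},
#'   \code{gene}, \code{status}, \code{low_confidence}, \code{provenance}.
#' @slot note scope note describing what the fixture covers.
#' @export
setClass("CuratedFixture",
  representation(
    name = "character",
    tree = "ANY",
    records = "data.frame",
    note = "character"
  )
)

setValidity("CuratedFixture", function(object) {
  msgs <- character(0)
  r <- object@records
  need <- c("species", "taxon_group", "gene", "status", "low_confidence",
            "provenance")
  if (!all(need %in% names(r)))
    msgs <- c(msgs, paste("records must have columns:",
                          paste(need, collapse = ", ")))
  else {
    if (!all(r$status %in% GENE_STATUSES))
      msgs <- c(msgs, "status values must be one of the four gene statuses")
    if (anyDuplicated(r[, c("species", "gene")]))
      msgs <- c(msgs, "at most one record per (species, gene)")
    if (any(!nzchar(r$provenance)))
      msgs <- c(msgs, "every record must carry a provenance note")
  }
  if (!inherits(object@tree, "phylo"))
    msgs <- c(msgs, "tree must be an ape 'phylo' object")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CuratedFixture", function(object) {
  cat("CuratedFixture:", object@name, "\n",
      length(object@tree$tip.label), "tree tips;",
      length(unique(object@records$species)), "curated species x",
      length(unique(object@records$gene)), "genes\n ", object@note, "\n")
})

#' @describeIn CuratedFixture-class curated status records.
#' @param x a \code{CuratedFixture}.
#' @export
fixtureRecords <- function(x) {
  stopifnot(is(x, "CuratedFixture"))
  x@records
}

#' @describeIn CuratedFixture-class the species tree.
#' @export
fixtureTree <- function(x) {
  stopifnot(is(x, "CuratedFixture"))
  x@tree
}
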