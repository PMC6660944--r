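## Fewest-event (Dollo) gene-loss reconstruction on rooted species trees.
##
## Model: a gene arises once (it is present in the analysis clade's
## ancestor) and can only be lost, irreversibly. Under this model the
## minimal reconstruction scores each internal node present iff any
## descendant tip is present, and charges one loss on every branch whose
## parent is present and whose child is absent — i.e. one event per
## maximal all-absent clade.

checkRootedTree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("'tree' must be an ape 'phylo' object")
  if (!ape::is.rooted(tree))
    stop("'tree' must be rooted")
  if (anyDuplicated(tree$tip.label))
    stop("tip labels must be unique")
  invisible(tree)
}

# deterministic per-node labels: tips use their tip label; internal nodes
# use their node label when present, otherwise "N<preorder rank>" --
# stable across runs for the same newick string
nodeIdVector <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ids <- character(ntip + nnode)
  ids[seq_len(ntip)] <- tree$tip.label
  edges <- reorder(tree, "cladewise")$edge
  pre <- unique(as.vector(t(edges)))           # preorder node sequence
  rank <- setNames(seq_along(pre), pre)
  for (v in (ntip + 1L):(ntip + nnode)) {
    lab <- if (!is.null(tree$node.label)) tree$node.label[v - ntip] else ""
    ids[v] <- if (!is.na(lab) && nzchar(lab)) lab
              else paste0("N", rank[[as.character(v)]])
  }
  if (anyDuplicated(ids))
    stop("node labels collide with tip labels or each other: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  ids
}

#' Branch identifiers of a rooted tree in deterministic preorder
#'
#' Each branch is identified by its child node: the tip label for terminal
#' branches, the internal node label (or \code{"N<preorder rank>"} when
#' unlabelled) for internal branches. The pseudo-branch subtending the
#' root (the "root stem") has the reserved id \code{"ROOT"} and is not
#' included here.
#'
#' @param tree rooted \code{ape::phylo} tree.
#' @return Character vector of branch ids in preorder.
#' @export
branchIds <- function(tree) {
  checkRootedTree(tree)
  ids <- nodeIdVector(tree)
  edges <- reorder(tree, "cladewise")$edge
  ids[edges[, 2L]]
}

#' Minimal gene-loss events on a rooted tree (Dollo reconstruction)
#'
#' Places the provably minimal set of irreversible loss events explaining
#' a binary tip presence/absence vector under a single-origin model. With
#' \code{assumeRootPresent = TRUE} (default) the gene is taken to be
#' present in the clade's common ancestor, so a gene absent from every tip
#' is charged exactly one loss on the root stem (branch id \code{"ROOT"}).
#' With \code{assumeRootPresent = FALSE} root presence is the OR of the
#' tip states, and a gene that never occurs incurs no loss.
#'
#' @param tree rooted \code{ape::phylo} tree.
#' @param states named 0/1 vector; names must be exactly the tree's tips
#'   (1 = gene present).
#' @param assumeRootPresent logical, see above.
#' @return A list with \code{branches} (character vector of branch ids
#'   bearing one loss each, in preorder), \code{count} (the minimal number
#'   of losses) and \code{nodePresence} (named 0/1 vector over all nodes of
#'   the reconstruction).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' dolloLosses(tr, c(A = 1, B = 0, C = 0, D = 0))$count  # 2
#' @export
dolloLosses <- function(tree, states, assumeRootPresent = TRUE) {
  checkRootedTree(tree)
  tips <- tree$tip.label
  miss <- setdiff(tips, names(states))
  if (length(miss))
    stop("missing tip state for: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(states), tips)
  if (length(extra))
    stop("states given for unknown tips: ", paste(extra, collapse = ", "))
  st <- assertBinaryVector(unname(states[tips]), "states")

  ntip <- length(tips)
  nnode <- tree$Nnode
  pres <- integer(ntip + nnode)
  pres[seq_len(ntip)] <- as.integer(st)
  post <- reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(post))) {           # parent present iff any tip below
    p <- post[i, 1L]; ch <- post[i, 2L]
    if (pres[ch] == 1L) pres[p] <- 1L
  }

  ids <- nodeIdVector(tree)
  root <- ntip + 1L
  losses <- character(0)
  if (pres[root] == 0L) {
    if (assumeRootPresent) losses <- "ROOT"   # forced single stem loss
  } else {
    pre <- reorder(tree, "cladewise")$edge
    drop <- pres[pre[, 1L]] == 1L & pres[pre[, 2L]] == 0L
    losses <- ids[pre[drop, 2L]]
  }
  names(pres) <- ids
  list(branches = losses, count = length(losses), nodePresence = pres)
}

#' Build the binary loss-event table for several genes on one tree
#'
#' Runs \code{\link{dolloLosses}} per gene and assembles the binary code
#' table: rows are the branches on which at least one gene is lost (root
#' stem first, then deterministic preorder), columns are genes, and entry
#' (branch, gene) is 1 iff that gene is lost on that branch under the
#' minimal reconstruction.
#'
#' @param tree rooted \code{ape::phylo} tree.
#' @param statesByGene named list of tip-state vectors (one per gene), or a
#'   0/1 matrix with species rows and gene columns.
#' @param assumeRootPresent passed to \code{\link{dolloLosses}}.
#' @return A \code{\linkS4class{LossEventTable}}.
#' @export
buildEventTable <- function(tree, statesByGene, assumeRootPresent = TRUE) {
  if (is.matrix(statesByGene)) {
    statesByGene <- setNames(
      lapply(seq_len(ncol(statesByGene)), function(j)
        setNames(statesByGene[, j], rownames(statesByGene))),
      colnames(statesByGene))
  }
  if (!length(statesByGene) || is.null(names(statesByGene)) ||
      any(!nzchar(names(statesByGene))))
    stop("'statesByGene' must be a non-empty named list of tip-state vectors")
  genes <- names(statesByGene)
  per <- lapply(statesByGene, function(s)
    dolloLosses(tree, s, assumeRootPresent = assumeRootPresent))
  order_all <- c("ROOT", branchIds(tree))
  used <- unique(unlist(lapply(per, `[[`, "branches")))
  rows <- order_all[order_all %in% used]
  ev <- matrix(0L, nrow = length(rows), ncol = length(genes),
               dimnames = list(rows, genes))
  for (g in genes) ev[per[[g]]$branches, g] <- 1L
  LossEventTable(ev)
}

descendantTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    ch <- kids[[as.character(v)]]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  tree$tip.label[out]
}

#' Collapse taxonomically labelled clades with uniform gene content
#'
#' Every internal node carrying a (clade) label whose tips all share an
#' identical gene-status vector is replaced by a single tip named after
#' the label and carrying that shared vector; clades with mixed content
#' are left expanded. Labelled clades must not be nested.
#'
#' @param tree rooted \code{ape::phylo} tree with clade labels as internal
#'   node labels.
#' @param states matrix with species rows (matching tip labels) and gene
#'   columns; values may be statuses or 0/1.
#' @return List with elements \code{tree} and \code{states} (reduced).
#' @export
collapseUniformClades <- function(tree, states) {
  checkRootedTree(tree)
  if (is.null(rownames(states)))
    stop("'states' must have species row names")
  miss <- setdiff(tree$tip.label, rownames(states))
  if (length(miss))
    stop("missing states for tips: ", paste(miss, collapse = ", "))
  labs <- tree$node.label
  if (is.null(labs) || !any(nzchar(labs) & !is.na(labs)))
    return(list(tree = tree, states = states))

  ntip <- length(tree$tip.label)
  lnodes <- which(nzchar(labs) & !is.na(labs)) + ntip
  tipsets <- lapply(lnodes, descendantTips, tree = tree)
  names(tipsets) <- labs[lnodes - ntip]
  # nested labelled clades would make the collapse ambiguous
  for (i in seq_along(tipsets)) for (j in seq_along(tipsets)) {
    if (i < j && length(intersect(tipsets[[i]], tipsets[[j]])))
      stop("overlapping labelled clades: ", names(tipsets)[i], " and ",
           names(tipsets)[j])
  }

  st <- states
  tr <- tree
  for (lab in names(tipsets)) {
    tipset <- tipsets[[lab]]
    block <- st[tipset, , drop = FALSE]
    uniform <- all(apply(block, 2L, function(col) length(unique(col)) == 1L))
    if (!uniform || length(tipset) < 2L) next
    keep <- tipset[1L]
    tr <- ape::drop.tip(tr, setdiff(tipset, keep),
                        collapse.singles = TRUE)
    tr$tip.label[tr$tip.label == keep] <- lab
    rownames(st)[rownames(st) == keep] <- lab
    st <- st[setdiff(rownames(st), setdiff(tipset, keep)), , drop = FALSE]
  }
  # drop the consumed clade labels so repeated calls are stable
  if (!is.null(tr$node.label))
    tr$node.label[tr$node.label %in% tr$tip.label] <- ""
  list(tree = tr, states = st[tr$tip.label, , drop = FALSE])
}
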