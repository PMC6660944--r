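## Readers and writers for the pipeline's plain-text formats: TSV domain
## tables, TSV status/state matrices, TSV loss-event tables, newick trees
## (via ape) and JSON reports (via jsonlite).

#' Read a domain-architecture table
#'
#' Expects a TSV with columns \code{species}, \code{sequence_id},
#' \code{family_hint}, \code{domains} (semicolon-separated tokens) and
#' \code{tm_count}; an optional \code{pseudogene} (TRUE/FALSE) column is
#' honoured.
#'
#' @param path TSV file path.
#' @return List of \code{\linkS4class{DomainRecord}} objects.
#' @export
readDomainTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "sequence_id", "family_hint", "domains", "tm_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("domain table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"pseudogene" %in% names(df)) df$pseudogene <- FALSE
  lapply(seq_len(nrow(df)), function(i) {
    toks <- strsplit(df$domains[i], ";", fixed = TRUE)[[1]]
    DomainRecord(df$species[i], df$sequence_id[i], df$family_hint[i],
                 domains = trimws(toks[nzchar(trimws(toks))]),
                 tmCount = df$tm_count[i],
                 pseudogene = isTRUE(as.logical(df$pseudogene[i])))
  })
}

#' Classify a domain-record collection into a per-species status table
#'
#' @param records list of \code{\linkS4class{DomainRecord}} objects
#'   (possibly several species) or a TSV path for
#'   \code{\link{readDomainTable}}.
#' @return data.frame with columns \code{species}, \code{CatSper},
#'   \code{sNHE}, \code{sAC}, \code{pattern}.
#' @export
classifyDomainTable <- function(records) {
  if (is.character(records)) records <- readDomainTable(records)
  sp <- vapply(records, function(r) r@species, character(1))
  out <- lapply(split(records, sp), function(rs) {
    st <- classifySpecies(rs)
    data.frame(species = rs[[1]]@species,
               CatSper = st[["CatSper"]], sNHE = st[["sNHE"]],
               sAC = st[["sAC"]], pattern = attr(st, "pattern"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}

#' Turn long-format status records into a species x gene matrix
#'
#' @param records data.frame with columns \code{species}, \code{gene},
#'   \code{status} (e.g. \code{\link{fixtureRecords}} output).
#' @return Character matrix of statuses, species rows, gene columns.
#' @export
statusMatrix <- function(records) {
  genes <- unique(records$gene)
  species <- unique(records$species)
  m <- matrix(NA_character_, length(species), length(genes),
              dimnames = list(species, genes))
  m[cbind(records$species, records$gene)] <- records$status
  if (anyNA(m))
    stop("incomplete status table: every (species, gene) cell is required")
  m
}

#' Binary presence matrix from a status matrix or records
#'
#' @param x status matrix (\code{\link{statusMatrix}}) or long-format
#'   records data.frame.
#' @return Integer 0/1 matrix (1 = gene present).
#' @export
presenceMatrix <- function(x) {
  if (is.data.frame(x)) x <- statusMatrix(x)
  out <- matrix(binaryPresence(x), nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

#' Read/write a tip-state (presence) matrix as TSV
#'
#' Rows are species (first column \code{species}), remaining columns are
#' genes with 0/1 or status values.
#'
#' @param path TSV file path.
#' @return For the reader, a matrix with species row names.
#' @export
readStateMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "species")
    stop("state matrix must have 'species' as its first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  m
}

#' @rdname readStateMatrix
#' @param m matrix to write.
#' @export
writeStateMatrix <- function(m, path) {
  df <- data.frame(species = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a loss-event table as TSV
#'
#' First column \code{branch}, remaining columns 0/1 per gene.
#'
#' @param path TSV file path.
#' @return For the reader, a \code{\linkS4class{LossEventTable}}.
#' @export
readEventTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "branch")
    stop("event table must have 'branch' as its first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$branch
  LossEventTable(m)
}

#' @rdname readEventTable
#' @param table a \code{\linkS4class{LossEventTable}}.
#' @export
writeEventTable <- function(table, path) {
  ev <- eventMatrix(table)
  df <- data.frame(branch = rownames(ev), ev, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise coevolution results to JSON
#'
#' @param results named list of \code{\linkS4class{CoevolutionResult}}
#'   objects (\code{\link{pairwiseCoevolution}} output).
#' @param path output path; omit to get the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
coevolutionJSON <- function(results, path = NULL) {
  payload <- lapply(results, function(r) {
    list(pair = r@pair, r = r@rObserved, p = r@pEmpirical,
         n_perm = r@nPermutations, seed = r@seed, tail = r@tail,
         note = r@note)
  })
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
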