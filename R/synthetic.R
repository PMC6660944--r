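## Seeded synthetic-data generators with known ground truth: Yule trees,
## coupled/independent irreversible gene-loss histories, domain records
## engineered to classify to a requested pattern, and degraded genomic
## loci embedding pseudogene-like remnants of a reference protein.

#' Simulate a rooted Yule (pure-birth) species tree
#'
#' @param nTips number of tips (>= 2).
#' @param seed integer seed; identical seeds give byte-identical newick.
#' @return A rooted binary \code{ape::phylo} tree with unique tip names
#'   \code{t1..tn}.
#' @export
simulateTree <- function(nTips, seed) {
  if (length(nTips) != 1L || is.na(nTips) || nTips < 2L)
    stop("'nTips' must be a single integer >= 2")
  withSeed(seed, ape::rphylo(as.integer(nTips), birth = 1, death = 0))
}

#' Configuration for a coupled gene-loss simulation
#'
#' @param genes gene names.
#' @param pLoss per-branch independent loss probability per gene, in
#'   [0, 1).
#' @param kappa per-branch shared-loss probability in [0, 1): with this
#'   probability a single event deletes every still-present gene of the
#'   coupled set on that branch.
#' @param coupled subset of \code{genes} subject to the shared event
#'   (default: all genes).
#' @param seed integer seed.
#' @return A validated configuration list of class
#'   \code{"lossSimConfig"}.
#' @export
lossSimConfig <- function(genes, pLoss, kappa = 0, coupled = genes, seed) {
  if (!is.character(genes) || !length(genes) || anyDuplicated(genes))
    stop("'genes' must be unique gene names")
  if (pLoss < 0 || pLoss >= 1) stop("'pLoss' must be in [0, 1)")
  if (kappa < 0 || kappa > 1) stop("'kappa' must be in [0, 1]")
  if (!all(coupled %in% genes))
    stop("'coupled' must be a subset of 'genes'")
  if (missing(seed)) stop("'seed' is required")
  structure(list(genes = genes, pLoss = pLoss, kappa = kappa,
                 coupled = coupled, seed = as.integer(seed)),
            class = "lossSimConfig")
}

#' Simulate irreversible gene loss along a rooted tree
#'
#' All genes are present at the root. Branches are visited in preorder;
#' on each branch a shared event (probability \code{kappa}) first deletes
#' every still-present coupled gene, then each still-present gene is
#' independently lost with probability \code{pLoss}. Loss is irreversible
#' down the subtree. The exact event history is returned alongside the
#' tip matrix, as ground truth for loss-reconstruction and correlation
#' analyses.
#'
#' @param tree rooted \code{ape::phylo} tree.
#' @param config a \code{\link{lossSimConfig}}.
#' @return List with \code{tips} (0/1 matrix, species x genes),
#'   \code{events} (data.frame of branch/gene loss events, with a
#'   \code{shared} flag), and \code{eventMatrix} (0/1 matrix over all
#'   branches x genes; row names are \code{\link{branchIds}}).
#' @export
simulateLosses <- function(tree, config) {
  stopifnot(inherits(config, "lossSimConfig"))
  checkRootedTree(tree)
  genes <- config$genes
  edges <- reorder(tree, "cladewise")$edge
  ids <- nodeIdVector(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  withSeed(config$seed, {
    state <- matrix(1L, nrow = ntip + tree$Nnode, ncol = length(genes),
                    dimnames = list(NULL, genes))
    evm <- matrix(0L, nrow = nrow(edges), ncol = length(genes),
                  dimnames = list(ids[edges[, 2L]], genes))
    shared <- logical(0)
    evRows <- list()
    for (i in seq_len(nrow(edges))) {
      p <- edges[i, 1L]; ch <- edges[i, 2L]
      st <- state[p, ]
      sharedHit <- config$kappa > 0 && runif(1) < config$kappa
      if (sharedHit) {
        for (g in intersect(config$coupled, genes[st == 1L])) {
          st[g] <- 0L
          evm[i, g] <- 1L
          evRows[[length(evRows) + 1L]] <-
            data.frame(branch = ids[ch], gene = g, shared = TRUE,
                       stringsAsFactors = FALSE)
        }
      }
      for (g in genes) {
        if (st[g] == 1L && config$pLoss > 0 && runif(1) < config$pLoss) {
          st[g] <- 0L
          evm[i, g] <- 1L
          evRows[[length(evRows) + 1L]] <-
            data.frame(branch = ids[ch], gene = g, shared = FALSE,
                       stringsAsFactors = FALSE)
        }
      }
      state[ch, ] <- st
    }
    tips <- state[seq_len(ntip), , drop = FALSE]
    rownames(tips) <- tree$tip.label
    events <- if (length(evRows)) do.call(rbind, evRows)
              else data.frame(branch = character(0), gene = character(0),
                              shared = logical(0), stringsAsFactors = FALSE)
    list(tips = tips, events = events, eventMatrix = evm)
  })
}

#' Generate domain records that classify to a requested pattern code
#'
#' Emits \code{\linkS4class{DomainRecord}} objects for one synthetic
#' species whose classification (via \code{\link{classifySpecies}}) yields
#' a status triple consistent with the requested pattern: e.g.
#' \code{"Int3"} produces four intact CatSper alpha subunits, an NHE
#' lacking the voltage-sensor domain, and a qualifying soluble adenylyl
#' cyclase. Absent genes are realised in varied ways (fewer than four
#' alpha subunits, CNBD-only homologues, NTPase-less cyclases...) chosen
#' by the seed.
#'
#' @param pattern one of \code{"All"}, \code{"None"}, \code{"Int1"},
#'   \code{"Int2"}, \code{"Int3"}; \code{"Other"} is ambiguous and an
#'   error.
#' @param seed integer seed.
#' @param species species name for the records.
#' @return List of \code{\linkS4class{DomainRecord}} objects.
#' @export
simulateDomainRecords <- function(pattern, seed, species = "synthetic_sp") {
  if (!pattern %in% c("All", "None", "Int1", "Int2", "Int3"))
    stop("'pattern' must be one of All, None, Int1, Int2, Int3 ",
         "(Other is ambiguous)")
  want <- list(All = c(1, 1, 1), None = c(0, 0, 0), Int1 = c(0, 1, 1),
               Int2 = c(0, 0, 1), Int3 = c(1, 0, 1))[[pattern]]
  withSeed(seed, {
    recs <- list()
    nAlpha <- if (want[1] == 1) 4L + sample(0:1, 1) else sample(0:3, 1)
    for (i in seq_len(nAlpha))
      recs[[length(recs) + 1L]] <- DomainRecord(
        species, paste0("CatSper", i), "catsper_alpha",
        domains = character(0), tmCount = 6L)
    if (want[1] == 1)                       # auxiliaries never decide
      recs[[length(recs) + 1L]] <- DomainRecord(
        species, "CatSperBeta", "catsper_auxiliary", tmCount = 1L)
    nheDomains <- if (want[2] == 1) c("NHE_exchanger", "VSD", "CNBD")
      else switch(sample(3, 1),
                  c("NHE_exchanger", "CNBD"),   # homologue only
                  c("NHE_exchanger"),
                  NULL)                         # no NHE record at all
    if (!is.null(nheDomains))
      recs[[length(recs) + 1L]] <- DomainRecord(
        species, "NHE1", "nhe", domains = nheDomains, tmCount = 13L)
    acDomains <- if (want[3] == 1)
      c("AC_catalytic", "AC_catalytic", "P_loop_NTPase")
      else switch(sample(3, 1),
                  c("AC_catalytic", "AC_catalytic"),  # candidate homologue
                  c("AC_catalytic"),
                  NULL)
    acTm <- if (want[3] == 1) 0L else sample(c(0L, 6L), 1)
    if (!is.null(acDomains))
      recs[[length(recs) + 1L]] <- DomainRecord(
        species, "AC1", "ac", domains = acDomains, tmCount = acTm)
    recs
  })
}

#' Configuration for a degraded-locus simulation
#'
#' @param reference reference protein sequence (character or
#'   \code{AAString}), non-empty, standard residues.
#' @param nExonSegments number of exon-like segments the coding sequence
#'   is split into (>= 1).
#' @param pointMutationRate per-nucleotide substitution probability in
#'   [0, 1).
#' @param frameshiftCount number of 1-nt insertions placed inside
#'   segments.
#' @param prematureStopCount number of internal codons converted to stop
#'   codons.
#' @param backgroundLength total fragment length in nt; must be at least
#'   the embedded coding length.
#' @param seed integer seed.
#' @return Validated configuration list of class
#'   \code{"degradedLocusConfig"}.
#' @export
degradedLocusConfig <- function(reference, nExonSegments = 3L,
                                pointMutationRate = 0.05,
                                frameshiftCount = 0L,
                                prematureStopCount = 0L,
                                backgroundLength = 3000L, seed) {
  if (is(reference, "AAString")) reference <- as.character(reference)
  assertString(reference, "reference")
  reference <- toupper(reference)
  aa <- strsplit(reference, "", fixed = TRUE)[[1]]
  if (!all(aa %in% names(AA_CODONS)))
    stop("reference contains non-standard residues: ",
         paste(unique(setdiff(aa, names(AA_CODONS))), collapse = ", "))
  if (nExonSegments < 1L) stop("'nExonSegments' must be >= 1")
  if (pointMutationRate < 0 || pointMutationRate >= 1)
    stop("'pointMutationRate' must be in [0, 1)")
  if (frameshiftCount < 0L || prematureStopCount < 0L)
    stop("counts must be non-negative")
  if (missing(seed)) stop("'seed' is required")
  embedded <- 3L * nchar(reference) + frameshiftCount
  if (backgroundLength < embedded)
    stop("impossible embedding: backgroundLength (", backgroundLength,
         ") < embedded coding length (", embedded, ")")
  structure(list(reference = reference,
                 nExonSegments = as.integer(nExonSegments),
                 pointMutationRate = pointMutationRate,
                 frameshiftCount = as.integer(frameshiftCount),
                 prematureStopCount = as.integer(prematureStopCount),
                 backgroundLength = as.integer(backgroundLength),
                 seed = as.integer(seed)),
            class = "degradedLocusConfig")
}

AA_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[setdiff(unique(gc), "*")]
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a genomic fragment containing a degraded gene remnant
#'
#' Reverse-translates the reference protein (uniform choice among
#' synonymous codons), splits the coding sequence into
#' \code{nExonSegments} contiguous segments, degrades it with point
#' mutations, premature stop codons and 1-nt frameshift insertions, and
#' embeds the segments, in order and non-overlapping, in seeded random
#' background DNA. Returns the fragment together with exact truth
#' intervals: one row per maximal constant-frame run, giving 0-based
#' half-open genomic and reference-protein coordinates and the reading
#' frame.
#'
#' @param config a \code{\link{degradedLocusConfig}}.
#' @return List with \code{fragment} (list: \code{id}, \code{sequence})
#'   and \code{truth} (data.frame: \code{segment}, \code{gStart},
#'   \code{gEnd}, \code{pStart}, \code{pEnd}, \code{frame}).
#' @export
simulateDegradedLocus <- function(config) {
  stopifnot(inherits(config, "degradedLocusConfig"))
  withSeed(config$seed, {
    aa <- strsplit(config$reference, "", fixed = TRUE)[[1]]
    nAA <- length(aa)
    k <- min(config$nExonSegments, nAA)
    bounds <- round(seq(0, nAA, length.out = k + 1L))
    segProt <- cbind(start = bounds[-(k + 1L)], end = bounds[-1L])

    codons <- vapply(aa, function(a) {
      cs <- AA_CODONS[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1))

    if (config$prematureStopCount > 0L) {
      # internal codons only, so segment boundaries stay intact
      cand <- setdiff(seq_len(nAA), c(segProt[, "start"] + 1L,
                                      segProt[, "end"]))
      stopAt <- sample(cand, min(config$prematureStopCount, length(cand)))
      codons[stopAt] <- sample(STOP_CODONS, length(stopAt), replace = TRUE)
    } else stopAt <- integer(0)

    # per-base point substitutions, codon-wise and stop-avoiding: stop
    # formation is controlled solely by prematureStopCount, so a
    # substitution that would create an in-frame stop is redirected
    bases <- c("A", "C", "G", "T")
    for (ci in setdiff(seq_len(nAA), stopAt)) {
      ch <- strsplit(codons[ci], "", fixed = TRUE)[[1]]
      hit <- which(runif(3L) < config$pointMutationRate)
      for (j in hit) ch[j] <- sample(setdiff(bases, ch[j]), 1L)
      if (length(hit)) {
        cod <- paste(ch, collapse = "")
        if (cod %in% STOP_CODONS) {
          for (b in bases) {           # deterministic non-stop repair
            cod2 <- paste0(substr(cod, 1, 2), b)
            if (!cod2 %in% STOP_CODONS) { cod <- cod2; break }
          }
        }
        codons[ci] <- cod
      }
    }

    segDNA <- lapply(seq_len(k), function(i) {
      paste(codons[(segProt[i, "start"] + 1L):segProt[i, "end"]],
            collapse = "")
    })

    # frameshifts: 1-nt insertions at interior cut points of segments; a
    # cut point c (0-based) puts the inserted base at final index c + the
    # number of earlier insertions, splitting the coding run at c. Cuts
    # keep every resulting run at least 25 codons long, so each run is a
    # detectable exon-like unit rather than an unrecoverable stub.
    margin <- 75L
    fsBySeg <- vector("list", k)
    if (config$frameshiftCount > 0L) {
      eligible <- which(vapply(segDNA, nchar, integer(1)) >= 2L * margin)
      if (!length(eligible))
        stop("impossible embedding: segments too short for frameshifts")
      segIdx <- sample(rep(eligible, length.out = config$frameshiftCount))
      for (i in seq_len(k)) {
        nfs <- sum(segIdx == i)
        if (!nfs) next
        L0 <- nchar(segDNA[[i]])
        cand <- seq(margin, L0 - margin)
        cuts <- integer(0)
        for (f in seq_len(nfs)) {
          if (!length(cand)) break
          cut <- sample(cand, 1L)
          cuts <- c(cuts, cut)
          cand <- cand[abs(cand - cut) >= margin]
        }
        cuts <- sort(cuts)
        fsBySeg[[i]] <- cuts
        ch <- strsplit(segDNA[[i]], "", fixed = TRUE)[[1]]
        for (q in rev(cuts))
          ch <- append(ch, sample(bases, 1L), after = q)
        segDNA[[i]] <- paste(ch, collapse = "")
      }
    }

    segLens <- vapply(segDNA, nchar, integer(1))
    total <- sum(segLens)
    slack <- config$backgroundLength - total
    # distribute the non-coding slack over k+1 gaps
    cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, slack))
    starts <- cumsum(gaps[seq_len(k)] + c(0L, segLens[-k]))

    background <- sample(bases, config$backgroundLength, replace = TRUE)
    # assemble: background with segments spliced in at 'starts'
    pieces <- character(0)
    bgPos <- 0L
    for (i in seq_len(k)) {
      pieces <- c(pieces,
                  paste(background[seq_len(gaps[i]) + bgPos], collapse = ""),
                  segDNA[[i]])
      bgPos <- bgPos + gaps[i]
    }
    pieces <- c(pieces, paste(background[seq_len(gaps[k + 1L]) + bgPos],
                              collapse = ""))
    sequence <- paste(pieces, collapse = "")

    # truth rows: one per maximal constant-frame coding run. Run r of a
    # segment covers pre-insertion coding offsets [cut_{r-1}, cut_r); its
    # complete codons are residues ceil(a/3) .. floor(b/3), shifted in the
    # final fragment by the r-1 insertions upstream of it.
    truth <- list()
    for (i in seq_len(k)) {
      s0 <- starts[i]
      L0 <- 3L * (segProt[i, "end"] - segProt[i, "start"])
      cuts <- c(0L, fsBySeg[[i]], L0)
      for (r in seq_len(length(cuts) - 1L)) {
        a <- cuts[r]; b <- cuts[r + 1L]
        jmin <- as.integer(ceiling(a / 3))
        jmax <- b %/% 3L                       # exclusive residue bound
        if (jmax <= jmin) next
        gStart <- s0 + 3L * jmin + (r - 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          segment = i,
          gStart = gStart, gEnd = s0 + 3L * jmax + (r - 1L),
          pStart = segProt[i, "start"] + jmin,
          pEnd = segProt[i, "start"] + jmax,
          frame = (gStart %% 3L) + 1L,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    list(fragment = list(id = "synthetic_degraded_locus",
                         sequence = sequence),
         truth = truth)
  })
}
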