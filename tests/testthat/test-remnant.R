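# Six-frame translation, exon-candidate search, chaining

revTranslate <- function(protein) {
  # uniform reverse translation, independent of the generator module
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(protein, "")[[1]], function(a)
    names(gc)[gc == a][1], character(1)), collapse = "")
}

translateInterval <- function(seq, gStart, gEnd, frame) {
  piece <- substr(seq, gStart + 1, gEnd)
  if (frame < 0)
    piece <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(piece)))
  as.character(Biostrings::translate(Biostrings::DNAString(piece)))
}

test_that("six-frame translation follows the standard code and frames", {
  tr <- sixFrameTranslate("ATGGCC")
  expect_identical(tr[["+1"]], "MA")
  expect_identical(tr[["-1"]], "GH")            # revcomp GGCCAT -> G, H
  # length arithmetic on a 7-mer
  tr7 <- sixFrameTranslate("ATGGCCA")
  expect_identical(nchar(tr7[["+1"]]), 2L)
  expect_identical(nchar(tr7[["+3"]]), 1L)
  # stops rendered as '*'
  expect_identical(sixFrameTranslate("TAA")[["+1"]], "*")
  expect_error(sixFrameTranslate("ATGXZC"), "position")
  expect_error(sixFrameTranslate("AT"), "3 nt")
})

test_that("an exact in-frame embedding is recovered as one perfect hit", {
  set.seed(101)
  ref <- randomProtein(100)
  coding <- revTranslate(substr(ref, 11, 40))   # residues [10, 40)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  frag <- paste0(bg(300), coding, bg(300))
  hits <- findExonCandidates(frag, ref)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$pStart, 10L)
  expect_identical(hits$pEnd, 40L)
  expect_equal(hits$pident, 100)
  expect_identical(hits$gStart, 300L)
  expect_identical(hits$gEnd, 390L)
})

test_that("reverse-strand embeddings are found with negative frames", {
  set.seed(102)
  ref <- randomProtein(80)
  coding <- revTranslate(ref)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(coding)))
  bg <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  frag <- paste0(bg, rc, bg)
  hits <- findExonCandidates(frag, ref)
  expect_gte(nrow(hits), 1L)
  expect_lt(hits$frame[1], 0)
  # round-trip: re-translating the stored interval reproduces the segment
  expect_identical(
    translateInterval(frag, hits$gStart[1], hits$gEnd[1], hits$frame[1]),
    hits$segment[1])
})

test_that("hit coordinates round-trip through re-translation in all frames", {
  set.seed(7)
  ref <- randomProtein(200)
  cfg <- degradedLocusConfig(ref, nExonSegments = 2,
                             pointMutationRate = 0.05,
                             frameshiftCount = 2, backgroundLength = 2500,
                             seed = 77)
  loc <- simulateDegradedLocus(cfg)
  hits <- findExonCandidates(loc$fragment, ref)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    expect_identical(
      translateInterval(loc$fragment$sequence, hits$gStart[i],
                        hits$gEnd[i], hits$frame[i]),
      hits$segment[i], info = paste("hit", i))
  }
})

test_that("a frameshift splits the embedding into abutting hits", {
  set.seed(8)
  ref <- randomProtein(150)
  cfg <- degradedLocusConfig(ref, nExonSegments = 1,
                             pointMutationRate = 0, frameshiftCount = 1,
                             backgroundLength = 1500, seed = 13)
  loc <- simulateDegradedLocus(cfg)
  expect_identical(nrow(loc$truth), 2L)
  expect_false(loc$truth$frame[1] == loc$truth$frame[2])
  hits <- findExonCandidates(loc$fragment, ref)
  expect_gte(nrow(hits), 2L)
  frames <- sort(unique(hits$frame))
  expect_gte(length(frames), 2L)
  ch <- chainHits(stitchRemnants(hits))
  # the chained hits jointly cover nearly the whole reference
  expect_gte(sum(ch$pEnd - ch$pStart), 0.9 * nchar(ref))
})

test_that("stitching keeps colinear hits and drops conflicting ones", {
  h <- data.frame(frame = 1L, gStart = c(0, 300), gEnd = c(90, 390),
                  pStart = c(0, 40), pEnd = c(30, 70),
                  score = c(100, 80), pident = 100,
                  segment = "X", hitId = 1:2)
  ch <- stitchRemnants(h, referenceLength = 100)
  expect_identical(nrow(chainHits(ch)), 2L)
  expect_equal(chainScore(ch), 180)
  expect_equal(referenceCoverage(ch), 0.6)

  # colinear in genome but inverted in protein order: keep the better one
  h2 <- h
  h2$pStart <- c(40, 0); h2$pEnd <- c(70, 30)
  ch2 <- stitchRemnants(h2, referenceLength = 100)
  expect_identical(nrow(chainHits(ch2)), 1L)
  expect_equal(chainHits(ch2)$score, 100)

  # empty input: empty chain, not an error
  ch0 <- stitchRemnants(h[integer(0), , drop = FALSE])
  expect_identical(nrow(chainHits(ch0)), 0L)
  expect_identical(chainScore(ch0), 0)
})

test_that("chaining matches brute-force best colinear subsets", {
  set.seed(303)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    pos <- sort(sample(0:400, n))
    len <- sample(5:30, n, replace = TRUE)
    h <- data.frame(frame = 1L,
                    gStart = pos * 3, gEnd = (pos + len) * 3,
                    pStart = sample(0:200, n), score = runif(n, 20, 120),
                    pident = 90, segment = "X", hitId = seq_len(n))
    h$pEnd <- h$pStart + len
    ch <- stitchRemnants(h, referenceLength = 300)
    dpScore <- sum(h$score[chainHits(ch)$hitId])
    expect_equal(dpScore, chainOracleScore(h), tolerance = 1e-9,
                 info = paste("rep", rep))
  }
})

test_that("site-coverage trimming applies the strict threshold", {
  # 4 rows, one column with a gap: coverage 0.75 < 0.8 -> removed
  aln4 <- c(a = "MK-V", b = "MKLV", c = "MKLV", d = "MKLV")
  out4 <- trimLowCoverageColumns(aln4, 0.8)
  expect_identical(unname(nchar(out4)), rep(3L, 4))
  # 5 rows, one column with one gap: coverage exactly 0.8 -> kept
  aln5 <- c(a = "MK-V", b = "MKLV", c = "MKLV", d = "MKLV", e = "MKLV")
  out5 <- trimLowCoverageColumns(aln5, 0.8)
  expect_identical(unname(nchar(out5)), rep(4L, 5))
  # gap-free alignment: identity
  expect_identical(trimLowCoverageColumns(aln5[-1]), aln5[-1])
  # all columns removed: warning and empty rows
  expect_warning(out0 <- trimLowCoverageColumns(
    c(a = "--", b = "A-", c = "-A", d = "--"), 0.8), "empty")
  expect_identical(unname(nchar(out0)), rep(0L, 4))
})

test_that("trimming is idempotent and preserves row names", {
  set.seed(44)
  for (rep in 1:10) {
    ncol <- sample(10:30, 1); nrow <- sample(3:8, 1)
    rows <- replicate(nrow, paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                    "")[[1]], "-", "-"),
                                         ncol, replace = TRUE),
                                  collapse = ""))
    names(rows) <- paste0("s", seq_len(nrow))
    once <- suppressWarnings(trimLowCoverageColumns(rows))
    twice <- suppressWarnings(trimLowCoverageColumns(once))
    expect_identical(once, twice)
    expect_identical(names(once), names(rows))
  }
})

test_that("column conservation distinguishes identity, similarity, neither", {
  aln <- c(r1 = "AIAD", r2 = "ALAK", r3 = "AVKF", r4 = "AMFA")
  lab <- columnConservation(aln)
  expect_identical(as.vector(lab), c("conserved", "similar", "conserved",
                                     "none"))
  # AAAA column conserved; ILVM all aliphatic -> similar; ADKF -> none
  expect_identical(as.vector(columnConservation(c(a = "A", b = "A", c = "A",
                                                  d = "A"))), "conserved")
  expect_identical(as.vector(columnConservation(c(a = "I", b = "L", c = "V",
                                                  d = "M"))), "similar")
  expect_identical(as.vector(columnConservation(c(a = "A", b = "D", c = "K",
                                                  d = "F"))), "none")
  # gaps are excluded from the denominator
  expect_identical(as.vector(columnConservation(c(a = "A", b = "A", c = "-",
                                                  d = "-"))), "conserved")
})

test_that("AAStringSet alignments are accepted and returned in kind", {
  aln <- Biostrings::AAStringSet(c(a = "MK-V", b = "MKLV", c = "MKLV",
                                   d = "MKLV"))
  out <- trimLowCoverageColumns(aln, 0.8)
  expect_s4_class(out, "AAStringSet")
  expect_identical(unique(Biostrings::width(out)), 3L)
  lab <- columnConservation(aln)
  expect_length(lab, 4L)
})
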