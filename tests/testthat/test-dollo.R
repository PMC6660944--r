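# Fewest-event loss reconstruction

test_that("dolloLosses places minimal losses on simple topologies", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  res <- dolloLosses(tr, c(A = 1, B = 0, C = 0, D = 0))
  expect_identical(res$count, 2L)
  expect_true("B" %in% res$branches)           # terminal loss
  expect_identical(as.integer(dolloOracle(tr, c(A = 1, B = 0, C = 0,
                                                D = 0))), 2L)

  expect_identical(dolloLosses(tr, c(A = 1, B = 1, C = 1, D = 1))$count, 0L)
  allAbsent <- c(A = 0, B = 0, C = 0, D = 0)
  expect_identical(dolloLosses(tr, allAbsent)$branches, "ROOT")
  expect_identical(dolloLosses(tr, allAbsent,
                               assumeRootPresent = FALSE)$count, 0L)
})

test_that("dolloLosses validates its inputs", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(dolloLosses(tr, c(A = 1, B = 0, C = 0)), "D")
  expect_error(dolloLosses(ape::unroot(tr),
                           c(A = 1, B = 0, C = 0, D = 0)), "rooted")
  expect_error(dolloLosses(tr, c(A = 2, B = 0, C = 0, D = 0)), "0 and 1")
})

test_that("dollo reconstruction equals exhaustive minimal-transition search", {
  set.seed(11)
  for (ntip in 4:5) {
    for (rep in 1:2) {
      tr <- ape::rtree(ntip)
      tr$tip.label <- LETTERS[seq_len(ntip)]
      for (mask in 0:(2^ntip - 1)) {
        st <- setNames(as.integer(intToBits(mask)[seq_len(ntip)]),
                       tr$tip.label)
        expect_identical(dolloLosses(tr, st)$count,
                         as.integer(dolloOracle(tr, st)),
                         info = paste("ntip", ntip, "mask", mask))
      }
    }
  }
})

test_that("polytomies charge one loss per absent child subtree", {
  tr <- ape::read.tree(text = "((A,B,C),(D,E));")
  res <- dolloLosses(tr, c(A = 1, B = 0, C = 0, D = 0, E = 0))
  expect_identical(res$count, 3L)               # B, C, (D,E) stem
  expect_identical(dolloOracle(tr, c(A = 1, B = 0, C = 0,
                                     D = 0, E = 0)), 3L)
  # a tree whose root is a basal polytomy is ambiguous and rejected
  expect_error(dolloLosses(ape::read.tree(text = "(A,B,C);"),
                           c(A = 1, B = 0, C = 0)), "rooted")
})

test_that("loss count equals number of maximal all-absent clades", {
  set.seed(21)
  for (rep in 1:20) {
    ntip <- sample(4:10, 1)
    tr <- ape::rtree(ntip)
    tr$tip.label <- paste0("t", seq_len(ntip))
    st <- setNames(randomNonConstant(ntip), tr$tip.label)
    res <- dolloLosses(tr, st)
    expect_gte(res$count, 0L)
    expect_lte(res$count, ntip)
    # every loss branch roots a clade scored absent
    for (b in res$branches)
      expect_identical(unname(res$nodePresence[b]), 0L)
  }
})

test_that("buildEventTable assembles per-gene losses into binary rows", {
  tr <- ape::read.tree(text = "((A,B),C);")
  # both genes lost only on the branch to B
  tab <- buildEventTable(tr, list(X = c(A = 1, B = 0, C = 1),
                                  Y = c(A = 1, B = 0, C = 1)))
  expect_identical(dim(tab), c(1L, 2L))
  expect_identical(unname(eventMatrix(tab)[1, ]), c(1L, 1L))
  expect_identical(eventBranches(tab), "B")

  # X lost on B, Y lost on C: two rows, complementary entries
  tab2 <- buildEventTable(tr, list(X = c(A = 1, B = 0, C = 1),
                                   Y = c(A = 1, B = 1, C = 0)))
  expect_identical(dim(tab2), c(2L, 2L))
  expect_identical(sort(eventBranches(tab2)), c("B", "C"))
  expect_identical(unname(colSums(eventMatrix(tab2))), c(1, 1))

  # nothing lost anywhere: zero rows
  tab3 <- buildEventTable(tr, list(X = c(A = 1, B = 1, C = 1)))
  expect_identical(nrow(eventMatrix(tab3)), 0L)

  expect_error(buildEventTable(tr, list()), "non-empty")
})

test_that("event-table column sums equal per-gene dollo counts", {
  set.seed(31)
  tr <- simulateTree(12, seed = 5)
  cfg <- lossSimConfig(genes = c("g1", "g2", "g3"), pLoss = 0.15,
                       kappa = 0, seed = 9)
  sim <- simulateLosses(tr, cfg)
  tab <- buildEventTable(tr, sim$tips)
  for (g in colnames(sim$tips)) {
    expect_identical(unname(colSums(eventMatrix(tab))[g]),
                     as.numeric(dolloLosses(tr, sim$tips[, g])$count))
  }
  if (nrow(eventMatrix(tab)) > 0)
    expect_true(all(rowSums(eventMatrix(tab)) >= 1))
})

test_that("uniform labelled clades collapse to single tips", {
  txt <- "(((m1,m2),(m3,(m4,m5)))Mammalia,((b1,b2)Aves,out));"
  tr <- ape::read.tree(text = txt)
  st <- matrix(1L, nrow = 8, ncol = 3,
               dimnames = list(c(paste0("m", 1:5), "b1", "b2", "out"),
                               c("CatSper", "sNHE", "sAC")))
  st["b1", "CatSper"] <- 0L                    # Aves mixed -> stays expanded
  red <- collapseUniformClades(tr, st)
  expect_true("Mammalia" %in% red$tree$tip.label)
  expect_false(any(paste0("m", 1:5) %in% red$tree$tip.label))
  expect_true(all(c("b1", "b2") %in% red$tree$tip.label))
  expect_identical(unname(red$states["Mammalia", "CatSper"]), 1L)

  # collapsing preserves per-gene loss counts
  pre <- dolloLosses(tr, setNames(st[, "CatSper"], rownames(st)))$count
  post <- dolloLosses(red$tree,
                      setNames(red$states[, "CatSper"],
                               rownames(red$states)))$count
  expect_identical(pre, post)

  # unlabelled tree: identity
  tr2 <- ape::read.tree(text = "((a,b),c);")
  st2 <- matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "g"))
  red2 <- collapseUniformClades(tr2, st2)
  expect_identical(red2$tree$tip.label, tr2$tip.label)
})

test_that("nested labelled clades are rejected", {
  tr <- ape::read.tree(text = "(((a,b)Inner,c)Outer,d);")
  st <- matrix(1L, 4, 1, dimnames = list(letters[1:4], "g"))
  expect_error(collapseUniformClades(tr, st), "overlapping")
})
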