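# Domain-rule orthologue classification

alphaRecs <- function(n, species = "sp", pseudo = rep(FALSE, n)) {
  lapply(seq_len(n), function(i)
    DomainRecord(species, paste0("CatSper", i), "catsper_alpha",
                 tmCount = 6L, pseudogene = pseudo[i]))
}
auxRecs <- function(n, species = "sp") {
  lapply(seq_len(n), function(i)
    DomainRecord(species, paste0("aux", i), "catsper_auxiliary"))
}

test_that("CatSper presence requires at least four intact alpha subunits", {
  expect_identical(classifyCatSper(c(alphaRecs(4), auxRecs(5))), "present")
  # Heliconius-like: two alpha subunits retained
  expect_identical(classifyCatSper(alphaRecs(2)), "absent")
  # ostrich-like: three alpha subunits retained
  expect_identical(classifyCatSper(alphaRecs(3)), "absent")
  expect_identical(classifyCatSper(list()), "absent")
  # auxiliary subunits never compensate
  expect_identical(classifyCatSper(c(alphaRecs(3), auxRecs(9))), "absent")
  # pseudogenic alpha subunits are not intact
  expect_identical(
    classifyCatSper(alphaRecs(5, pseudo = c(FALSE, FALSE, TRUE, TRUE, TRUE))),
    "absent")
  # duplicate sequence ids count once
  expect_identical(classifyCatSper(c(alphaRecs(3), alphaRecs(3))), "absent")
})

test_that("records from mixed species are rejected as malformed", {
  recs <- c(alphaRecs(2, "sp1"), alphaRecs(2, "sp2"))
  expect_error(classifyCatSper(recs), "multiple species")
})

test_that("sNHE orthology requires both VSD and CNBD", {
  mk <- function(doms) DomainRecord("sp", "n1", "nhe", domains = doms,
                                    tmCount = 13L)
  expect_identical(classifySlc9c(mk(c("NHE_exchanger", "VSD", "CNBD"))),
                   "present")
  # SOS1-like: CNBD without VSD
  expect_identical(classifySlc9c(mk(c("NHE_exchanger", "CNBD"))),
                   "homologue_only")
  expect_identical(classifySlc9c(mk("NHE_exchanger")), "absent")
  expect_error(classifySlc9c(DomainRecord("sp", "x", "ac")),
               "family mismatch")
})

test_that("sAC requires two catalytic domains, no TM and the NTPase domain", {
  mk <- function(doms, tm) DomainRecord("sp", "a1", "ac", domains = doms,
                                        tmCount = tm)
  two <- c("AC_catalytic", "AC_catalytic")
  expect_identical(classifySac(mk(c(two, "P_loop_NTPase"), 0L)), "present")
  expect_identical(classifySac(mk(two, 0L)), "homologue_only")
  expect_identical(classifySac(mk(two, 6L)), "absent")          # tmAC
  expect_identical(classifySac(mk("AC_catalytic", 0L)), "absent")
  expect_error(classifySac(DomainRecord("sp", "x", "nhe")),
               "family mismatch")
})

test_that("classification rules are monotone in their diagnostic features", {
  rank <- c(absent = 0L, homologue_only = 1L, present = 2L)
  # sNHE over all subsets of the diagnostic domains
  subsets <- list(character(0), "VSD", "CNBD", c("VSD", "CNBD"))
  for (s in subsets) for (add in c("VSD", "CNBD")) {
    if (add %in% s) next
    lo <- classifySlc9c(DomainRecord("sp", "n", "nhe",
                                     domains = c("NHE_exchanger", s)))
    hi <- classifySlc9c(DomainRecord("sp", "n", "nhe",
                                     domains = c("NHE_exchanger", s, add)))
    expect_gte(rank[hi], rank[lo])
  }
  # sAC: adding the NTPase domain to a qualifying candidate never demotes
  two <- c("AC_catalytic", "AC_catalytic")
  for (tm in c(0L, 6L)) {
    lo <- classifySac(DomainRecord("sp", "a", "ac", domains = two,
                                   tmCount = tm))
    hi <- classifySac(DomainRecord("sp", "a", "ac",
                                   domains = c(two, "P_loop_NTPase"),
                                   tmCount = tm))
    expect_gte(rank[hi], rank[lo])
  }
  # CatSper: adding an intact alpha subunit never demotes
  for (n in 0:5)
    expect_gte(rank[classifyCatSper(alphaRecs(n + 1L))],
               rank[classifyCatSper(alphaRecs(n))])
})

test_that("pattern codes cover the 8 binary triples, 5 named + 3 Other", {
  grid <- expand.grid(c = 0:1, s = 0:1, a = 0:1)
  codes <- mapply(patternCode, grid$c, grid$s, grid$a)
  expect_setequal(unique(codes),
                  c("All", "None", "Int1", "Int2", "Int3", "Other"))
  expect_identical(sum(codes == "Other"), 3L)
  expect_identical(patternCode(1, 1, 1), "All")
  expect_identical(patternCode(0, 0, 0), "None")
  expect_identical(patternCode(0, 1, 1), "Int1")
  expect_identical(patternCode(0, 0, 1), "Int2")
  expect_identical(patternCode(1, 0, 1), "Int3")
})

test_that("statuses collapse to binary: only 'present' counts as 1", {
  statuses <- c("present", "homologue_only", "pseudogene", "absent")
  for (s in statuses) {
    expected <- if (s == "present") "All" else "Int1"
    expect_identical(patternCode(s, "present", "present"), expected)
  }
  expect_identical(binaryPresence(statuses), c(1L, 0L, 0L, 0L))
  expect_error(binaryPresence("maybe"), "unknown gene status")
})

test_that("domain vocabulary is case-insensitive with aliases", {
  out <- normalizeDomainTokens(c("cnbd", "Voltage-sensor domain",
                                 "p-loop NTPase", "NHE", "Mystery_domain"))
  expect_identical(out[1:4], c("CNBD", "VSD", "P_loop_NTPase",
                               "NHE_exchanger"))
  expect_identical(attr(out, "unknown"), "Mystery_domain")
})
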