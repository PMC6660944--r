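## Domain-architecture orthologue classification.
##
## The rules encode the strict definitions used for presence calls:
##  - CatSper "present" needs >= 4 distinct intact pore-forming alpha
##    subunits (auxiliary subunits never compensate);
##  - an sNHE (SLC9C) orthologue needs both a voltage-sensor domain (VSD)
##    and a cyclic nucleotide-binding domain (CNBD); CNBD without VSD is a
##    homologue only (e.g. plant SOS1);
##  - an sAC (ADCY10) needs two adenylyl-cyclase catalytic domains, zero
##    transmembrane segments and a P-loop NTPase domain; without the NTPase
##    domain the protein is only a candidate homologue.

# canonical token -> aliases (all matched case-insensitively after
# squashing separators); upstream domain annotators vary in spelling
DOMAIN_ALIASES <- list(
  VSD = c("vsd", "voltagesensordomain", "voltagesensor"),
  CNBD = c("cnbd", "cyclicnucleotidebindingdomain", "cyclicnucleotidebinding",
           "cnbhd"),
  AC_catalytic = c("accatalytic", "accat", "adenylylcyclasecatalytic",
                   "cyclasecatalytic", "guanylatecyclase", "cyclasehomology"),
  P_loop_NTPase = c("ploopntpase", "ntpase", "ploop",
                    "ploopnucleosidetriphosphatehydrolase"),
  NHE_exchanger = c("nheexchanger", "nhe", "nahexchanger", "sodiumhydrogenexchanger",
                    "na_hexchanger")
)

#' Normalise domain tokens against the controlled vocabulary
#'
#' Matching is case-insensitive and ignores separator characters
#' (\code{-}, \code{_}, \code{.}, spaces), so \code{"p-loop NTPase"},
#' \code{"P_loop_NTPase"} and \code{"ploopntpase"} all map to
#' \code{"P_loop_NTPase"}. Tokens outside the vocabulary are preserved
#' verbatim and flagged with the attribute \code{"unknown"}.
#'
#' @param tokens character vector of raw domain names.
#' @return Character vector of canonical tokens, with attribute
#'   \code{"unknown"} listing unrecognised inputs (if any).
#' @examples
#' normalizeDomainTokens(c("cnbd", "Voltage-sensor domain", "NHE"))
#' @export
normalizeDomainTokens <- function(tokens) {
  if (!length(tokens)) return(character(0))
  squash <- function(x) gsub("[-_. ]", "", tolower(x))
  canon <- names(DOMAIN_ALIASES)
  lut <- setNames(rep(canon, lengths(DOMAIN_ALIASES)),
                  unlist(DOMAIN_ALIASES, use.names = FALSE))
  lut[squash(canon)] <- canon
  key <- squash(tokens)
  out <- unname(lut[key])
  unknown <- tokens[is.na(out)]
  out[is.na(out)] <- tokens[is.na(out)]
  if (length(unknown)) attr(out, "unknown") <- unique(unknown)
  out
}

hasDomain <- function(record, token) token %in% record@domains
countDomain <- function(record, token) sum(record@domains == token)

#' Classify CatSper presence from one species' channel-subunit records
#'
#' CatSper is a sperm-specific Ca2+ channel whose pore is a heterotetramer
#' of four distinct alpha subunits. A species is scored \code{"present"}
#' only if at least four distinct intact alpha-subunit records are found;
#' auxiliary (beta/gamma/delta...) subunits never compensate for missing
#' alpha subunits. Species retaining two or three intact alpha subunits
#' (e.g. the butterfly \emph{Heliconius melpomene}, the ostrich
#' \emph{Struthio camelus}) are scored \code{"absent"} under this rule.
#'
#' @param records list of \code{\linkS4class{DomainRecord}} objects, all
#'   from the same species; empty input returns \code{"absent"}.
#' @return \code{"present"} or \code{"absent"}.
#' @examples
#' recs <- lapply(1:4, function(i)
#'   DomainRecord("Mus_musculus", paste0("CatSper", i), "catsper_alpha"))
#' classifyCatSper(recs)  # "present"
#' @export
classifyCatSper <- function(records) {
  if (!length(records)) return("absent")
  if (!all(vapply(records, is, logical(1), "DomainRecord")))
    stop("'records' must be a list of DomainRecord objects")
  sp <- unique(vapply(records, function(r) r@species, character(1)))
  if (length(sp) != 1L)
    stop("malformed grouping: records span multiple species: ",
         paste(sp, collapse = ", "))
  alpha <- Filter(function(r) r@familyHint == "catsper_alpha" && !r@pseudogene,
                  records)
  nAlpha <- length(unique(vapply(alpha, function(r) r@sequenceId,
                                 character(1))))
  if (nAlpha >= 4L) "present" else "absent"
}

#' Classify an NHE record as sNHE orthologue, homologue or absent
#'
#' An sNHE (SLC9C) orthologue must carry both the voltage-sensor domain
#' (VSD) and the cyclic nucleotide-binding domain (CNBD). An NHE with a
#' CNBD but no VSD (such as \emph{Arabidopsis} SOS1) is a homologue only.
#'
#' @param record a \code{\linkS4class{DomainRecord}} with
#'   \code{familyHint == "nhe"}.
#' @return \code{"present"}, \code{"homologue_only"} or \code{"absent"}.
#' @examples
#' classifySlc9c(DomainRecord("sp", "x1", "nhe",
#'                            c("NHE_exchanger", "VSD", "CNBD")))
#' @export
classifySlc9c <- function(record) {
  stopifnot(is(record, "DomainRecord"))
  if (record@familyHint != "nhe")
    stop("family mismatch: classifySlc9c expects an 'nhe' record, got '",
         record@familyHint, "'")
  if (hasDomain(record, "VSD") && hasDomain(record, "CNBD")) "present"
  else if (hasDomain(record, "CNBD")) "homologue_only"
  else "absent"
}

#' Classify an adenylyl-cyclase record as sAC, candidate homologue or absent
#'
#' A soluble adenylyl cyclase (sAC/ADCY10) under the strict rule must have
#' exactly two catalytic domains, no transmembrane segments, and a P-loop
#' nucleoside-triphosphate-hydrolase (NTPase) domain. A two-domain,
#' TM-free cyclase lacking the NTPase domain is retained only as a
#' candidate (\code{"homologue_only"}); transmembrane cyclases are
#' \code{"absent"}.
#'
#' @param record a \code{\linkS4class{DomainRecord}} with
#'   \code{familyHint == "ac"}.
#' @return \code{"present"}, \code{"homologue_only"} or \code{"absent"}.
#' @examples
#' classifySac(DomainRecord("sp", "ac1", "ac",
#'   c("AC_catalytic", "AC_catalytic", "P_loop_NTPase"), tmCount = 0))
#' @export
classifySac <- function(record) {
  stopifnot(is(record, "DomainRecord"))
  if (record@familyHint != "ac")
    stop("family mismatch: classifySac expects an 'ac' record, got '",
         record@familyHint, "'")
  soluble2 <- countDomain(record, "AC_catalytic") == 2L &&
    record@tmCount == 0L
  if (!soluble2) return("absent")
  if (hasDomain(record, "P_loop_NTPase")) "present" else "homologue_only"
}

#' Collapse a gene status to binary presence
#'
#' \code{"present"} maps to 1; \code{"homologue_only"}, \code{"pseudogene"}
#' and \code{"absent"} all map to 0.
#'
#' @param status character vector of gene statuses.
#' @return Integer 0/1 vector.
#' @export
binaryPresence <- function(status) {
  bad <- setdiff(unique(status), GENE_STATUSES)
  if (length(bad))
    stop("unknown gene status: ", paste(bad, collapse = ", "))
  as.integer(status == "present")
}

#' Pattern code for a (CatSper, sNHE, sAC) status triple
#'
#' Species are grouped by which of the three genes are conserved:
#' \code{All} (1,1,1), \code{None} (0,0,0), \code{Int1} = sNHE + sAC
#' without CatSper (0,1,1), \code{Int2} = only sAC (0,0,1), \code{Int3} =
#' CatSper + sAC without sNHE (1,0,1). The remaining three binary triples
#' have no named group and code as \code{Other}. Statuses collapse to
#' binary presence first (\code{\link{binaryPresence}}).
#'
#' @param catsper,snhe,sac gene statuses (or 0/1 values).
#' @return One of \code{"All"}, \code{"None"}, \code{"Int1"},
#'   \code{"Int2"}, \code{"Int3"}, \code{"Other"}.
#' @examples
#' patternCode("present", "present", "present")  # "All"
#' patternCode("absent", "present", "present")   # "Int1"
#' @export
patternCode <- function(catsper, snhe, sac) {
  tobin <- function(s) {
    if (is.character(s)) binaryPresence(s) else assertBinaryVector(s, "status")
  }
  key <- paste(tobin(catsper), tobin(snhe), tobin(sac), sep = "")
  map <- c("111" = "All", "000" = "None", "011" = "Int1",
           "001" = "Int2", "101" = "Int3")
  out <- unname(map[key])
  out[is.na(out)] <- "Other"
  out
}

#' Classify all of one species' domain records into a status triple
#'
#' Routes records by \code{familyHint}: all \code{catsper_alpha} /
#' \code{catsper_auxiliary} records feed \code{\link{classifyCatSper}};
#' the best-scoring status over \code{nhe} records gives the sNHE status,
#' likewise \code{ac} records for sAC ("present" beats "homologue_only"
#' beats "absent").
#'
#' @param records list of \code{\linkS4class{DomainRecord}} objects for one
#'   species.
#' @return Named character vector with elements \code{CatSper},
#'   \code{sNHE}, \code{sAC}, plus attribute \code{"pattern"}.
#' @export
classifySpecies <- function(records) {
  hint <- vapply(records, function(r) r@familyHint, character(1))
  best <- function(statuses) {
    if (!length(statuses)) return("absent")
    ord <- c(present = 1L, homologue_only = 2L, pseudogene = 3L, absent = 4L)
    statuses[order(ord[statuses])][1L]
  }
  catsper <- classifyCatSper(records[hint %in% c("catsper_alpha",
                                                 "catsper_auxiliary")])
  snhe <- best(vapply(records[hint == "nhe"], classifySlc9c, character(1)))
  sac <- best(vapply(records[hint == "ac"], classifySac, character(1)))
  out <- c(CatSper = catsper, sNHE = snhe, sAC = sac)
  attr(out, "pattern") <- patternCode(catsper, snhe, sac)
  out
}
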