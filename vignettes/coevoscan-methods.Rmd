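---
title: "Methods: correlated gene loss of CatSper, sNHE and sAC"
author: "coevoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlated gene loss of CatSper, sNHE and sAC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The biological question

CatSper (the sperm-specific Ca²⁺ channel), sNHE/SLC9C (the sperm-specific
Na⁺/H⁺ exchanger, carrying a voltage-sensor domain and a cyclic
nucleotide-binding domain) and sAC/ADCY10 (the soluble adenylyl cyclase)
form a signalling module controlling sperm motility. All three genes predate
Metazoa, yet many animal lineages have lost one or more of them. If the
module functions as a unit, losses should be correlated: a lineage that
loses CatSper has less use for its activators. `coevoscan` provides the
machinery to score presence strictly, reconstruct minimal loss histories,
and test loss coupling — plus generators of synthetic data with known truth
to validate every step.

## Orthologue classification

Presence calls are deliberately strict, rule-based, and independent of
sequence similarity scores:

* **CatSper**: `present` iff ≥ 4 *distinct, intact* pore-forming α-subunit
  records exist for the species. Auxiliary subunits never substitute.
  Species retaining two or three α subunits (known real cases among
  butterflies and ratites) are `absent` under the rule — the channel is a
  heterotetramer of four different α subunits, so fewer cannot form the
  canonical pore.
* **sNHE**: `present` iff the NHE carries both VSD and CNBD; CNBD without
  VSD is `homologue_only` (the state of, e.g., plant SOS1); neither is
  `absent`.
* **sAC**: `present` iff two catalytic domains, zero transmembrane
  segments, and a P-loop NTPase domain; without the NTPase domain the
  protein remains a `homologue_only` candidate.

`pseudogene` is never assigned by these rules — the rules concern intact
proteins; pseudogene status comes from curation or from remnant scanning.
"Intact" means "not flagged pseudogenic"; no length threshold is imposed,
partial-length handling being a curation decision. The domain vocabulary is
case-insensitive with an alias table because upstream annotators vary in
spelling.

Pattern codes collapse statuses to binary (`present` → 1, everything else →
0) and name five of the eight triples: `All`, `None`, `Int1` (sNHE+sAC),
`Int2` (sAC only), `Int3` (CatSper+sAC). The remaining three triples get
`Other` rather than an invented name: no named group exists for them, and
inventing one would suggest an observation that was never made.

## Fewest-event loss reconstruction

The loss model is single-origin and irreversible (Dollo): the gene arises
once and can only be lost. Under this model the minimum-event
reconstruction is closed-form: score an internal node present iff any
descendant tip is present, and place one loss on each branch whose parent
is present and whose child is absent — equivalently, one loss per maximal
all-absent clade. The test suite proves minimality by exhaustive
enumeration of all internal-state assignments on every tree of 4–6 tips
crossed with every tip-state vector.

Two conventions matter:

* **Root state.** By default the analysis clade's ancestor is assumed to
  possess all three genes (`assumeRootPresent = TRUE`), because all three
  predate Metazoa; a gene absent from every tip then costs exactly one loss
  on the root stem (branch id `ROOT`). With the flag off, root presence is
  the OR of tip states and a never-present gene costs nothing.
* **Branch identity.** A branch is named by its child node — tip label,
  internal node label, or `N<preorder rank>` — which is stable across runs
  for the same newick string.

Statuses `homologue_only` and `pseudogene` code as 0 for loss inference: a
pseudogene is positive evidence the lineage once had the gene and lost it,
which is exactly what a loss event asserts. Polytomies are allowed and
charge one event per absent child subtree; no hidden resolution is
invented. Labelled clades whose tips share an identical status vector can
be collapsed to single tips (`collapseUniformClades`), which provably
preserves per-gene loss counts.

## Correlated-loss statistics

The association statistic for two binary loss vectors is Pearson's
product-moment correlation, i.e. the 2×2 phi coefficient. The null is
formed by randomly permuting one vector. Design choices:

* **Margin-preserving shuffling**, not i.i.d. Bernoulli resampling, is the
  default: it conditions on the observed number of loss events, which is
  the quantity the tree actually fixed. A `bernoulli` mode exists for
  sensitivity analysis; resamples that come out constant have an undefined
  statistic and are counted as not extreme.
* **Computation.** Under a uniform permutation the statistic depends on the
  permuted vector only through the overlap count n₁₁, which at fixed
  margins follows a hypergeometric law; draws are therefore taken directly
  from that law, and extremeness is decided in exact integer arithmetic
  (n·n₁₁ − n₁·n·₁ is monotone-linear in n₁₁), avoiding any floating-point
  tie ambiguity. The exhaustive oracle (`exhaustivePermutationP`, n ≤ 10)
  deliberately does **not** use this reduction — it enumerates position
  subsets and recomputes phi through the generic path — so the
  Monte-Carlo-vs-exact comparison in the tests is a genuine dual-route
  check.
* **Two-sided on |r|** by default; sidedness is a user choice.
* **Add-one correction**: p = (1 + #extreme)/(n_perm + 1), so p is never 0
  and equals 1 when every permutation is as extreme.
* **Defaults**: 500,000 permutations; the seed is mandatory.

### Calibration design

The type-I-error and power calibrations run on per-branch loss-event
indicator vectors over *all* branches of the simulated tree, not on the
union-filtered event table. Restricting rows to "branches with at least one
loss" structurally excludes (0,0) rows and induces negative dependence
between genes even when losses are simulated independently; that is a
property of the table construction, not of the test, so calibrating on the
full vectors isolates the statistic itself. The same consideration is worth
remembering when interpreting correlations computed on real event tables.

Calibration conditions (chosen once, as realistic for this kind of data):
a 64-tip Yule tree with per-branch loss probability 0.15 for the type-I
experiment — giving on the order of 15–25 events per gene across ~126
branches, enough distinct values of the permutation statistic for a
near-continuous p — and a 32-tip tree at loss rate 0.1 for the
coupling-monotonicity experiment over κ ∈ {0, 0.3, 0.6, 0.9}.

## Remnant scanning

A pseudogene remnant is detected as short translatable segments matching an
orthologous protein, interrupted by stops and frameshifts:

1. Six-frame translation (standard code, stops as `*`, N-codons as `X`,
   trailing partial codons dropped).
2. Each frame's translation is split into stop-free chunks; a remnant exon
   is by definition stop-free within a segment, and stops between segments
   are themselves the evidence of degradation. Chunks are locally aligned
   against the reference (BLOSUM62, gap open 11 / extend 1 — common
   translated-search defaults; `*` additionally scores −1000 so no
   alignment can contain a stop). Each accepted alignment is recorded and
   its flanks re-queued, so one chunk can yield several hits but no hit
   can bridge an already-claimed region. The splitting is essential, not
   cosmetic: gap columns bypass the substitution matrix, so blocking `*`
   alone would let an alignment bridge a stop-riddled gap through a long
   subject deletion.
3. Hits are mapped to 0-based half-open forward-strand genomic
   coordinates (negative frames store forward intervals plus the frame
   sign) and chained by O(n²) dynamic programming into the
   maximum-total-score subset that strictly advances in both genomic and
   protein coordinates. Overlaps of at most 9 nt between successive hits
   are tolerated during selection and resolved afterwards by trimming the
   lower-scoring hit in whole codons.

Score threshold 60 and minimum segment length 8 were calibrated on seeded
synthetic data only: a Karlin–Altschul estimate for the default problem
size (6 × ~1000 translated residues vs a 300-residue reference) puts the
95 % noise quantile near score 53, and the packaged calibration measures a
zero-hit rate on pure random background at or above 95 %. Conservation
labelling of alignment columns uses the fixed similarity classes
{AVLIM}, {FWY}, {ST}, {DE}, {KRH}, {NQ}, {GP}, {C}; site-coverage trimming
removes columns strictly below the threshold (a column at exactly 80 %
coverage is kept) and is idempotent.

## Synthetic-data generators

* **Trees**: Yule (pure-birth) topologies, seeded.
* **Loss histories**: preorder traversal; on each branch a shared event
  (probability κ) first deletes every still-present gene of the coupled
  set, then each still-present gene is lost independently with probability
  p. Shared and independent events can co-occur on a branch; drawing the
  shared event first keeps the independent-loss margin interpretable. The
  exact event history is returned as ground truth.
* **Domain records**: engineered to classify to a requested pattern code,
  with absent genes realised in varied ways (too few α subunits, CNBD-only
  homologues, NTPase-less cyclases); the round-trip through classification
  is asserted for all five named codes.
* **Degraded loci**: the reference protein is reverse-translated with
  uniform synonymous-codon choice (codon usage is irrelevant to the
  scanner's contract), split into exon-like segments, degraded with
  per-base point substitutions, engineered premature stops and 1-nt
  frameshift insertions, and embedded in order in seeded random background.
  Truth rows give one interval per maximal constant-frame run. Two
  deliberate constraints: point substitutions are stop-avoiding (a
  substitution that would create an in-frame stop is redirected), because
  stop formation is governed by the explicit `prematureStopCount` knob and
  uncontrolled stops would silently change the degradation level the
  configuration claims; and frameshift cut points keep every resulting run
  at least 25 codons, so each run is a detectable exon-like unit rather
  than an unrecoverable stub.

What the generators do *not* emulate: substitution-model sequence evolution
along the tree, rate heterogeneity, selection, codon bias, splice sites or
real intron structure. Passing recovery tests on these loci shows the
scanner finds degraded colinear remnants under controlled noise; it does
not show performance on real genomes with repeats, paralogues or
alignment-confounding composition.

## Curated fixtures

The packaged fixtures transcribe text-stated facts about the gene
distributions: a bird panel (CatSper conserved only in two Palaeognathae;
sNHE in no bird; sAC pseudogene remnants in turkey, duck and pigeon), a
12-species ray-finned-fish panel in which exactly three species conserve
all three genes (spotted gar plus two placeholder species not named in the
available text), an arthropod panel (lepidopterans as `Int1`, the fruit
fly with an sNHE remnant), and a group-level metazoan panel (uniform groups
as single tips; Mollusca `Int1`; *Trichoplax adhaerens* `Int2`). Rows not
backed by an explicit statement are flagged `low_confidence = TRUE` with a
`placeholder` provenance note; every row carries a short note naming its
supporting observation so the transcription is auditable. One
transcription decision: turkey is recorded with an sAC *pseudogene* (the
predicted-exon evidence), although one summary passage groups it with
chicken as conserving only sAC; the more specific statement won.

## Problem sizes and runtime

The test suite and acceptance script use: exhaustive Dollo verification on
trees of 4–6 tips × all state vectors; 50 Monte-Carlo-vs-exact permutation
comparisons at 200,000 permutations; 1,000 type-I simulations and 4 × 300–500
coupling replicates; 200–500 degraded loci (3 kb fragments, 300-residue
reference) and 100 background fragments. These sizes give stable estimates
while keeping a full run in a few minutes on one CPU.

## Known limitations

* Plain (non-phylogenetic) correlation of loss events: no correction for
  shared ancestry beyond conditioning on event counts; Pagel-style
  discrete-trait coevolution models are explicitly out of scope.
* The event-table row filter induces the dependence discussed above;
  comparisons across differently-filtered tables are not meaningful.
* The remnant chainer trims overlaps proportionally in whole codons, which
  is exact only for gapless hits.
* Fixtures are small curated panels; placeholder rows are conventions, not
  evidence, and are flagged as such.
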