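---
title: "Box C/D snoRNA motif annotation and k-turn functional classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box C/D snoRNA motif annotation and k-turn functional classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoKturn)
```

## The biological problem

Box C/D small nucleolar RNAs (snoRNAs) guide ribose 2'-O-methylation of
ribosomal RNA. Each guide RNA carries a terminal box C (consensus 5'-RUGAUGA,
R = A or G) near its 5' end and a terminal box D (5'-CUGA) near its 3' end;
together they fold into a kink-turn (k-turn), the binding platform for the
primary RNP assembly protein — Snu13 in eukaryotes, L7Ae in archaea. Archaeal
guide RNAs carry a second, internal box C'/D' motif pair that builds a second,
symmetric protein assembly site. In eukaryotes the predicted internal motifs
are poorly conserved, and whether they are *functional* — able to base-pair as
a k-turn (or k-loop) and recruit a second Snu13 copy — varies from snoRNA to
snoRNA. This package implements, as tested and reusable code, a
sequence-level procedure for (i) annotating the four boxes, (ii) evaluating
the structural features that decide protein recognizability, (iii)
classifying internal motifs into functional categories with census statistics
over snoRNA sets, (iv) predicting methylation target sites from guide
duplexes, and (v) ranking RNP stoichiometry hypotheses by theoretical mass.

## The k-turn coordinate frame

A k-turn placement is described by two windows: a box C'-like 7-mer and a box
D'-like 4-mer. Walking the 7-mer 5' to 3' gives slots L2, L3, b1...b5 (the
"b" strand of stem II, preceded by the bulged loop nucleotides); walking the
4-mer gives n4, n3, n2, n1 (the antiparallel "n" strand: ascending b index
pairs descending sequence position). Stem I lies outside the windows: pairs
−1 and −2 couple the two positions immediately 3' of the D'-like window
(minus1_n, minus2_n) with the positions 5' of L1 (minus1_b, minus2_b). Under
this map the consensus RUGAUGA/CUGA placement realizes the two tandem sheared
pairs that flank the kink, (b1,n1) = G•A and (b2,n2) = A•G, plus (b3,n3) =
U•U and (b4,n4) = G•C.

```{r frame}
seq <- paste0("AAAAAA", "CUGA", "GC", "AUCG", "GC", "A", "AUGAUGA", "AAAAAA")
fr <- buildKTurnFrame(seq, cStart = 20, dStart = 7, motifKind = "internal")
evaluateFeatures(fr, seq)
```

Feature semantics, and the choices behind them:

* **Sheared pairs** are nucleotide-identity checks (exactly G with A, A with
  G), not geometry predictions: the classification criteria are sequence
  level, and treating them as anything else would overstate what the code
  knows.
* **Stem I integrity** admits Watson–Crick *and* G•U wobble pairs: genuine
  k-turn stems can open with a wobble, and an experimentally characterized
  stem I beginning with G•U would otherwise be misread as broken.
* **k-loop** is declared only when *both* −1 and −2 pairs fail or are absent.
  A failed −1 above an intact −2 is a broken stem, not a loop; this
  conservative reading keeps the k-loop label for motifs genuinely lacking a
  stem.
* `N` never counts as a pairing partner: any pair involving `N` or an
  out-of-range position evaluates to `ABSENT` and therefore false.

**Coordinates.** Everything user-facing — and, unlike some pipelines, also
everything internal — is 1-based inclusive, the R/Bioconductor convention
(IRanges, Biostrings). The "fifth nucleotide upstream" arithmetic is 1-based
counting in the field's own usage, so no off-by-one translation layer exists
anywhere in the package. BED exports are 0-based half-open by the format's
definition; the conversion is delegated to `rtracklayer`.

## Box annotation rules

* **Box C**: best RUGAUGA match among windows starting within 5 nt of the 5'
  end (offsets 0..5), at most 1 mismatch by default (configurable); ties go
  to the smaller start.
* **Box D / D'**: exact CUGA. D boxes are treated as strictly conserved, so
  no mismatch allowance exists for them. When a known methylation target is
  supplied, only the occurrence starting exactly five nucleotides downstream
  of the guide position paired with the target is kept. Without target
  information, box D defaults to the 3'-most CUGA in the final 15 nt.
* **Box C'**: among all 7-mer windows between box D' and the guide upstream
  of box D, the window maximizing the stem II identity score (0–4, one point
  per canonical pair identity) is selected; ties break by fewer mismatches to
  RUGAUGA, then by smaller start. Stem II is scored over four pair positions:
  the b5 partner lies outside the 4-mer box D' window, so a fifth position
  would have to be scored against an arbitrary flank.
* **Box D' without target information**: every CUGA between box C and box D
  is a candidate, and the (D' candidate, C' window) pair maximizing the stem
  II score is chosen jointly, ties going to the 5'-most D'. This fills the
  gap left by anchoring D' annotation to known targets, which generic inputs
  lack.
* The C' window must start at least three positions past the D' end (keeping
  the two stem I slots free) and end at least `minGapToD = 6` nt before box D
  — a minimal guide reserved upstream of box D; the value is configurable
  because no hard minimum is established, and real guides are longer.
* When no candidate C' window reaches a stem II score of 1, the snoRNA is
  annotated as having **no credible box C'/D'** instead of forcing a window:
  fabricating a motif from a score-0 window would claim sequence evidence
  that is not there.

`windowOffset()` formalizes comparisons between alternative annotations of
the same region: the smallest shift by which one window's suffix tiles the
other's prefix. Re-annotations of internal motifs, e.g. after inspecting a
protein-bound structure, typically move the window by small offsets (three
nucleotides in the characterized cases), and the function makes that
displacement a computable quantity rather than prose.

## Functional classification

The classification rules encode the experimentally determined requirements
for protein recognition:

| category | rule |
|---|---|
| CANONICAL | both windows match the consensus |
| FUNCTIONAL_NONCANONICAL | both sheared pairs present and −1 pair intact |
| TANDEM_NO_STEM1 | both sheared pairs present, −1 pair missing |
| MISSING_SHEARED | at least one sheared pair missing |
| NO_MOTIF | no credible annotation |

"Functional" means CANONICAL or FUNCTIONAL_NONCANONICAL. NO_MOTIF records
count as non-functional in the census percentage, since the census contrasts
functional motifs with everything else.

The binding predicates are qualitative tiers, not affinities:

* **Snu13**: BINDER requires both sheared pairs, an intact −1 pair *and* a
  maximal stem II identity score; with the three required features but a
  degraded stem II the call is WEAK. The criteria are treated as necessary
  but not sufficient for strong binding because a construct satisfying all
  three was observed to bind only weakly, with band smearing. A real
  limitation follows from this design: a construct with a perfect stem II
  and all three features is always called BINDER, although at least one
  such engineered construct has been reported not to bind detectably —
  sequence features outside the scored positions evidently matter, and the
  model does not capture them.
* **L7Ae**: BINDER requires the 1b•1n sheared pair plus either an intact −1
  pair or the 2b•2n pair; the k-loop case carrying only the 1b•1n pair is
  WEAK (fast-dissociating, smearing); anything else is NONBINDER.

`klPanelFeatures()` bundles the construct panel these predicates were
calibrated against — the native-derived k-turn/k-loop constructs of snR51,
snR41 and snR54, their mutant series, an archaeal k-loop control and a
consensus control — as feature sets reconstructed from the constructs'
described secondary structures, with the observed EMSA tiers. One Snu13
observation is recorded as `NA` (not established in the main panel data) and
is not asserted anywhere.

`kdUpperBound()` computes the one quantitative EMSA-derived number: complete
displacement at a 1:1 protein:RNA ratio implies a dissociation constant at
least an order of magnitude below the total RNA concentration, so the bound
is `rna_total / 10` (200 nM at the 2 µM assay concentration). Lower bounds
from non-binding lanes are *not* computed: the reported non-binding bounds
use inconsistent factors between experiments, so they are left as
descriptive statements.

## Methylation target prediction

The guide region immediately 5' of a D box pairs a substrate antiparallel;
the methylated substrate nucleotide is the one paired with guide position
`boxStart − 5`. Duplex search requires the guide side to end exactly at
`boxStart − 1` and allows no internal gaps (guides form contiguous helices);
ties between equal-length duplexes go to more Watson–Crick pairs, then to the
5'-most substrate window. Wobble pairs are allowed inside the duplex by
default but rejected at the target-paired position (configurable): a wobble
at the catalytic register is not an established substrate geometry, so the
conservative default refuses to predict through one. The search is verified
in the test suite against a brute-force oracle enumerating every (offset,
length) pairing.

## RNP mass bookkeeping

`polymerMass()` sums average residue masses plus one water; the residue
tables are versioned constants (IUPAC 2021 average atomic weights). RNA
defaults to a 5'-OH end; the 5'-triphosphate option adds 3 × HPO₃ =
239.94 Da, below the 0.1 kDa at which particle masses are reported, so the
choice does not affect any reported value. Assembly masses are exact
stoichiometric sums, and `rankStoichiometries()` orders hypotheses by
absolute deviation from an observed (e.g. SEC-MALS) mass, with stable ties.

The bundled `inst/extdata/synthetic_rnp_components.fasta` contains
**synthetic stand-in** sequences, not the natural proteins and RNAs: each
stand-in is a random-composition polymer sized to the documented molecular
weight of the corresponding component (scaffold protein ~46.9 kDa,
methyltransferase ~25.8 kDa, Snu13 ~13.6 kDa, guide RNAs of 108 and 64 nt).
Agreement of the assembly sums with the documented particle masses (193.7 /
179.7 / 193.3 kDa) therefore validates the mass arithmetic and the ranking
logic, not any natural sequence; analyses of real constructs should supply
their own FASTA. Even with true accession sequences a ~1% tolerance would be
appropriate, since tag remnants after protease cleavage and exact construct
boundaries are rarely knowable from sequence databases alone.

## The synthetic benchmark generator

`simulateSnoRNAs()` emulates the guide RNA architecture
`5'-[tail]-boxC-[guide]-boxD'-[stem I]-[spacer]-[stem I]-boxC'-[guide]-boxD-[tail]-3'`
with uniform-ACGU background, 12-nt guides (the optimal archaeal
spacer/guide length), a 5-nt spacer, 0–3 nt tails, and per-category edits at
frame positions: consensus windows for CANONICAL; a consensus-breaking L3
substitution (which touches no pair) for FUNCTIONAL_NONCANONICAL; the same
plus a broken −1 pair (and, for half the records by default, a broken −2
pair, giving k-loops) for TANDEM_NO_STEM1; a b-side sheared-pair knockout
(b1 or b2, as in the native non-functional motifs) for MISSING_SHEARED; and
a CUGA-free interior for NO_MOTIF. Sheared-pair knockouts are made on the
b side only, because the n side *is* the box D' CUGA — mutating it would
delete the box rather than the pair. Each substrate is the exact reverse
complement of its guide with 2-nt random flanks, placing the planted target
at substrate position 7 in the default geometry.

The default category mix is the reported composition of the 43 yeast
methylation-guide snoRNAs (2 canonical : 6 near-canonical : 18 tandem
without stem I : 17 missing a sheared pair); proportions convert to integer
counts by deterministic largest-remainder apportionment.

**Ambiguity guard.** After planting, each record is re-annotated from its
bare sequence; the record is regenerated unless box C, box D, the (D', C')
placement, the category, and both methylation targets are recovered *and* no
alternative placement ties the planted stem II score. This makes "100%
recovery on unambiguous records" a well-defined property rather than a
statistical aspiration. `applyConstructEdit()` reproduces the mutant-series
edits (introduce the 2b•2n pair, remove the −1 pair, replace stem I by a
loop) as minimal substitutions at frame positions, updating the truth labels.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: covariation and evolutionary sequence structure,
secondary-structure-constrained backgrounds, imperfect guide–substrate
complementarity, modified nucleotides, and annotation ambiguity itself (real
snoRNAs can tie; the guard removes ties by construction). Recovery rates on
real snoRNA sets will be bounded by annotation ambiguity, not by the code
paths tested here.

## Census reproduction and its scope

Applying the pipeline to a 43-record synthetic set at the reported
composition recovers the full partition from bare sequence:

```{r census}
labeled <- simulateSnoRNAs(43, seed = 105)
cls <- classifyRecords(lapply(labeled, function(x) x@record))
census(cls)
```

This exercises the complete annotate → classify → census path, including the
headline numbers (2 canonical, at most 8 functional, >80% non-functional).
It is a synthetic reconstruction: reproducing the census on the *actual* 43
yeast snoRNAs requires their sequences from the external yeast snoRNA
database, which are not redistributable with the package. With those
sequences local, the same two calls (optionally with known-target TSVs to
anchor the D' boxes to the database placements) perform the census; where
the joint-optimization heuristic disagrees with a curated database
placement, supplying the known targets makes the database placement win.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery properties at 800
records (200 per motif category) plus 200 no-motif records, and the duplex
oracle comparison at 1000 random instances — sizes at which every code path
and tie-break fires many times while a full run stays comfortably
interactive. Mass identities are asserted to 1e-6 Da (floating-point
round-off only). All randomness flows through explicit seeds; the pipeline
itself is deterministic, and reports embed the package version, a config
hash and the coordinate convention.

## Known limitations

* Classification uses only the −1 stem I pair, per the stated criteria; the
  −2 pair enters only the k-loop call. If intact stems really require −2 as
  well, some FUNCTIONAL_NONCANONICAL calls are optimistic.
* The Snu13 BINDER tier can overcall engineered constructs (see above).
* No probabilistic motif models, no covariance search, no folding
  thermodynamics: annotation is strictly rule-based, by design.
* NO_MOTIF absorbs records lacking any credible CUGA candidate; on real
  data this category may overlap with what manual annotation would call a
  degenerate MISSING_SHEARED motif.
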