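# snoKturn

Annotation and functional classification of box C/D snoRNA kink-turn motifs.

Box C/D small nucleolar RNAs guide ribose 2'-O-methylation of rRNA. Their
terminal box C (5'-RUGAUGA) and box D (5'-CUGA) motifs fold into a kink-turn
(k-turn) that recruits the primary assembly protein (Snu13 in eukaryotes,
L7Ae in archaea). Internal box C'/D' motif pairs — canonical in archaea,
poorly conserved in eukaryotes — may or may not build a second protein
assembly site. `snoKturn` is for RNA biologists who need to decide, from
sequence, which internal motifs are *functional*: it annotates the four
boxes, maps the k-turn coordinate frame (stem I pairs −1/−2, loop L1–L3,
stem II pairs 1b•1n … 5b•5n) onto them, and classifies each internal site by
the experimentally established criteria

> Snu13-recognizable k-turn ⇔ 1b•1n G•A sheared pair ∧ 2b•2n A•G sheared
> pair ∧ intact −1 pair of stem I,

with census statistics over snoRNA sets. It also predicts 2'-O-methylation
target sites by the fifth-nucleotide rule (the substrate nucleotide paired
with guide position `boxD start − 5`), computes theoretical average masses of
RNP assemblies for stoichiometry ranking against SEC-MALS observations,
derives order-of-magnitude K_D bounds from EMSA saturation, and ships a
labelled synthetic snoRNA generator so every stage is testable without
external data.

## Worked example

Generate a 43-snoRNA set at the composition reported for the yeast
methylation-guide snoRNAs, then annotate and classify from bare sequence:

```r
library(snoKturn)
labeled <- simulateSnoRNAs(43, seed = 105)
recs <- lapply(labeled, function(x) x@record)

annotateBoxes(recs[[3]])
#> SnoRNAAnnotation for 'syn0003_functional_noncanonical'
#>   C         [2-8] GUGAUGA
#>   Dprime    [21-24] CUGA
#>   Cprime    [35-41] AGGAUGA
#>   D         [54-57] CUGA

census(classifyRecords(recs))
#> CensusReport over 43 snoRNAs
#>   canonical:                2
#>   functional noncanonical:  6
#>   tandem, no stem I:        18
#>   missing a sheared pair:   17
#>   no motif:                 0
#>   non-functional:           81.4%
```

Coordinates are 1-based inclusive. The census says: of 43 guide RNAs, only
the 2 canonical and 6 near-canonical internal motifs satisfy the
recognizability criteria — 81.4% of the predicted box C'/D' motifs are
non-functional. An EMSA that fully shifts the RNA at a 1:1 protein ratio
bounds the dissociation constant:

```r
kdUpperBound(2)   # 2 uM total RNA
#> AffinityBound: K_D <= 200 nM (saturating_ratio, total RNA 2 uM)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/snokturn.R` (subcommands `annotate`, `classify`, `census`,
`methylsite`, `mass`, `simulate`, `benchmark`).

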