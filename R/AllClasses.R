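#' @import methods
NULL

.RNA_ALPHABET <- c("A", "C", "G", "U", "N")

.MOTIF_CATEGORIES <- c("CANONICAL", "FUNCTIONAL_NONCANONICAL", "TANDEM_NO_STEM1",
                       "MISSING_SHEARED", "NO_MOTIF")

.BOX_KINDS <- c("C", "D", "Dprime", "Cprime")

#' SnoRNARecord: one snoRNA sequence
#'
#' Holds a single snoRNA sequence with a normalized RNA alphabet
#' (\code{A,C,G,U,N}, uppercase), optional experimentally known methylation
#' targets, and free-text provenance. All coordinates handled by the package
#' are 1-based inclusive.
#'
#' @slot id character(1) identifier.
#' @slot seq character(1) RNA sequence over \code{A,C,G,U,N}.
#' @slot knownTargets data.frame with columns \code{substrate_id},
#'   \code{position} (1-based), \code{box_kind} (\code{"D"} or \code{"Dprime"});
#'   may have zero rows.
#' @slot source character(1) free-text provenance.
#' @exportClass SnoRNARecord
setClass("SnoRNARecord",
         representation(id = "character", seq = "character",
                        knownTargets = "data.frame", source = "character"),
         prototype(knownTargets = data.frame(substrate_id = character(),
                                             position = integer(),
                                             box_kind = character(),
                                             stringsAsFactors = FALSE),
                   source = ""))

setValidity("SnoRNARecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) != 1L || !nzchar(object@seq))
    msg <- c(msg, "'seq' must be a single non-empty string")
  else {
    chars <- strsplit(object@seq, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% .RNA_ALPHABET)
    if (length(bad))
      msg <- c(msg, sprintf("illegal character '%s' at position %d (alphabet is A,C,G,U,N)",
                            chars[bad[1L]], bad[1L]))
  }
  kt <- object@knownTargets
  need <- c("substrate_id", "position", "box_kind")
  if (!all(need %in% names(kt)))
    msg <- c(msg, "knownTargets must have columns substrate_id, position, box_kind")
  else if (nrow(kt)) {
    if (any(kt$position < 1L)) msg <- c(msg, "knownTargets positions must be >= 1")
    if (!all(kt$box_kind %in% c("D", "Dprime")))
      msg <- c(msg, "knownTargets box_kind must be 'D' or 'Dprime'")
  }
  if (length(msg)) msg else TRUE
})

#' KTurnFrame: k-turn coordinate frame
#'
#' Maps the named k-turn positions (stem I pairs -1/-2, loop L1-L3, stem II
#' pairs 1b-5b / 1n-5n) onto 1-based sequence coordinates for one placement of
#' a box C'-like 7-mer window and a box D'-like 4-mer window. Slots that fall
#' outside the sequence are flagged absent.
#'
#' @slot positions named integer vector of 1-based sequence coordinates.
#' @slot absent named logical vector, TRUE where a slot lies outside the
#'   sequence.
#' @slot motifKind \code{"internal"} (box C'/D') or \code{"terminal"}
#'   (box C/D).
#' @slot seqLength integer(1) length of the parent sequence.
#' @exportClass KTurnFrame
setClass("KTurnFrame",
         representation(positions = "integer", absent = "logical",
                        motifKind = "character", seqLength = "integer"))

.FRAME_SLOTS <- c("minus2_b", "minus1_b", "L1", "L2", "L3",
                  "b1", "b2", "b3", "b4", "b5",
                  "n5", "n4", "n3", "n2", "n1", "minus1_n", "minus2_n")

.CORE_SLOTS <- c("b1", "b2", "b3", "b4", "b5", "n1", "n2", "n3", "n4")

setValidity("KTurnFrame", function(object) {
  msg <- character()
  if (!identical(sort(names(object@positions)), sort(.FRAME_SLOTS)))
    msg <- c(msg, "positions must be named with the full k-turn slot set")
  if (!identical(sort(names(object@absent)), sort(.FRAME_SLOTS)))
    msg <- c(msg, "absent flags must cover the full k-turn slot set")
  if (!object@motifKind %in% c("internal", "terminal"))
    msg <- c(msg, "motifKind must be 'internal' or 'terminal'")
  if (length(msg) == 0L && any(object@absent[.CORE_SLOTS]))
    msg <- c(msg, "core stem II slots (b1..b5, n1..n4) must lie inside the sequence")
  if (length(msg)) msg else TRUE
})

#' FeatureSet: structural features of one k-turn placement
#'
#' Boolean/integer evaluation of the sequence features that the functional
#' classification rules consume: the two sheared pairs of stem II, the -1/-2
#' pairs of stem I, k-loop status, consensus identity of the two windows, and
#' the stem II identity score (0-4).
#'
#' @slot hasSheared1 logical(1): b1=G paired with n1=A (the 1b.1n sheared pair).
#' @slot hasSheared2 logical(1): b2=A paired with n2=G (the 2b.2n sheared pair).
#' @slot stem1Minus1 logical(1): -1 pair of stem I is Watson-Crick or G:U wobble.
#' @slot stem1Minus2 logical(1): -2 pair of stem I is Watson-Crick or G:U wobble.
#' @slot isKloop logical(1): both stem I pairs fail or are absent.
#' @slot cprimeConsensus logical(1): 7-mer window matches RUGAUGA (R = A or G).
#' @slot dprimeConsensus logical(1): 4-mer window equals CUGA.
#' @slot stem2Score integer(1) in 0..4, see [scoreStemII()].
#' @exportClass FeatureSet
setClass("FeatureSet",
         representation(hasSheared1 = "logical", hasSheared2 = "logical",
                        stem1Minus1 = "logical", stem1Minus2 = "logical",
                        isKloop = "logical", cprimeConsensus = "logical",
                        dprimeConsensus = "logical", stem2Score = "integer"))

setValidity("FeatureSet", function(object) {
  sc <- object@stem2Score
  if (length(sc) != 1L || is.na(sc) || sc < 0L || sc > 4L)
    return("stem2Score must be a single integer in 0..4")
  TRUE
})

#' BoxAnnotation: one annotated box motif
#'
#' @slot boxKind one of \code{"C"}, \code{"D"}, \code{"Dprime"}, \code{"Cprime"}.
#' @slot start,end 1-based inclusive coordinates on the snoRNA.
#' @slot windowSeq the annotated window sequence (7 nt for C/C', 4 nt for D/D').
#' @slot mismatches integer(1) mismatches to the RUGAUGA consensus (C/C' boxes;
#'   0 for exact-match D boxes).
#' @slot score integer(1) stem II score (C' selection; \code{NA} otherwise).
#' @slot selectionRank integer(1) rank among candidates (1 = selected).
#' @exportClass BoxAnnotation
setClass("BoxAnnotation",
         representation(boxKind = "character", start = "integer", end = "integer",
                        windowSeq = "character", mismatches = "integer",
                        score = "integer", selectionRank = "integer"))

setValidity("BoxAnnotation", function(object) {
  msg <- character()
  if (!object@boxKind %in% .BOX_KINDS) msg <- c(msg, "unknown boxKind")
  wid <- object@end - object@start + 1L
  if (object@boxKind %in% c("C", "Cprime") && wid != 7L)
    msg <- c(msg, "C/C' windows must be 7 nt")
  if (object@boxKind %in% c("D", "Dprime") && wid != 4L)
    msg <- c(msg, "D/D' windows must be 4 nt")
  if (length(msg)) msg else TRUE
})

#' SnoRNAAnnotation: all annotated boxes of one snoRNA
#'
#' Container for the (possibly partial) box annotation of one snoRNA: boxes C
#' and D at the termini, the selected internal D'/C' pair, the k-turn frames
#' built on them, and annotation notes (tie-breaks taken, failures).
#'
#' @slot snornaId character(1).
#' @slot boxC,boxDprime,boxCprime,boxD a [BoxAnnotation-class] or \code{NULL}.
#' @slot internalFrame,terminalFrame a [KTurnFrame-class] or \code{NULL}.
#' @slot notes character vector of log messages.
#' @exportClass SnoRNAAnnotation
setClass("SnoRNAAnnotation",
         representation(snornaId = "character", boxC = "ANY", boxDprime = "ANY",
                        boxCprime = "ANY", boxD = "ANY", internalFrame = "ANY",
                        terminalFrame = "ANY", notes = "character"))

#' MotifClassification: functional category of one motif site
#'
#' @slot snornaId character(1).
#' @slot site \code{"internal"} (box C'/D') or \code{"terminal"} (box C/D).
#' @slot category one of CANONICAL, FUNCTIONAL_NONCANONICAL, TANDEM_NO_STEM1,
#'   MISSING_SHEARED, NO_MOTIF.
#' @slot functional logical(1); TRUE iff category is CANONICAL or
#'   FUNCTIONAL_NONCANONICAL.
#' @slot features a [FeatureSet-class], or \code{NULL} for NO_MOTIF.
#' @slot evidence character vector of rule firings.
#' @exportClass MotifClassification
setClass("MotifClassification",
         representation(snornaId = "character", site = "character",
                        category = "character", functional = "logical",
                        features = "ANY", evidence = "character"))

setValidity("MotifClassification", function(object) {
  msg <- character()
  if (!object@category %in% .MOTIF_CATEGORIES) msg <- c(msg, "unknown category")
  expected <- object@category %in% c("CANONICAL", "FUNCTIONAL_NONCANONICAL")
  if (!identical(object@functional, expected))
    msg <- c(msg, "functional flag must equal (category is CANONICAL or FUNCTIONAL_NONCANONICAL)")
  if (length(msg)) msg else TRUE
})

#' CensusReport: category counts over a snoRNA set
#'
#' @slot nTotal,nCanonical,nFunctionalNoncanonical,nTandemNoStem1,nMissingSheared,nNoMotif
#'   integer counts; they sum to \code{nTotal}.
#' @slot fractionNonfunctional percentage (0-100) of motifs that are neither
#'   CANONICAL nor FUNCTIONAL_NONCANONICAL.
#' @exportClass CensusReport
setClass("CensusReport",
         representation(nTotal = "integer", nCanonical = "integer",
                        nFunctionalNoncanonical = "integer",
                        nTandemNoStem1 = "integer", nMissingSheared = "integer",
                        nNoMotif = "integer", fractionNonfunctional = "numeric"))

setValidity("CensusReport", function(object) {
  tot <- object@nCanonical + object@nFunctionalNoncanonical +
    object@nTandemNoStem1 + object@nMissingSheared + object@nNoMotif
  if (tot != object@nTotal) return("category counts must sum to nTotal")
  TRUE
})

#' AffinityBound: order-of-magnitude K_D bound from an EMSA titration
#'
#' @slot direction \code{"upper"} or \code{"lower"}.
#' @slot value bound in nM.
#' @slot basis \code{"saturating_ratio"} or \code{"nonbinding_ratio"}.
#' @slot rnaTotal total RNA concentration of the assay, in uM.
#' @exportClass AffinityBound
setClass("AffinityBound",
         representation(direction = "character", value = "numeric",
                        basis = "character", rnaTotal = "numeric"))

setValidity("AffinityBound", function(object) {
  if (object@value <= 0) return("bound must be positive")
  TRUE
})

#' Component: a protein or RNA component with computed average mass
#'
#' @slot name character(1).
#' @slot kind \code{"protein"} or \code{"rna"}.
#' @slot sequence one-letter sequence.
#' @slot massTableVersion version tag of the residue-mass table used.
#' @slot mass average mass in Da (residues + one water).
#' @exportClass Component
setClass("Component",
         representation(name = "character", kind = "character",
                        sequence = "character", massTableVersion = "character",
                        mass = "numeric"))

setValidity("Component", function(object) {
  if (!object@kind %in% c("protein", "rna")) return("kind must be 'protein' or 'rna'")
  if (object@mass <= 0) return("mass must be positive")
  TRUE
})

#' AssemblyModel: a stoichiometry hypothesis for an RNP particle
#'
#' @slot name character(1).
#' @slot components list of [Component-class] objects.
#' @slot copies integer vector of copy numbers (>= 1), parallel to
#'   \code{components}.
#' @slot mass total average mass in Da (sum of copies x component mass).
#' @exportClass AssemblyModel
setClass("AssemblyModel",
         representation(name = "character", components = "list",
                        copies = "integer", mass = "numeric"))

setValidity("AssemblyModel", function(object) {
  msg <- character()
  if (length(object@components) != length(object@copies))
    msg <- c(msg, "components and copies must be parallel")
  if (length(object@copies) && any(object@copies < 1L))
    msg <- c(msg, "copy numbers must be >= 1")
  if (length(object@components) &&
      !all(vapply(object@components, is, logical(1), "Component")))
    msg <- c(msg, "components must be Component objects")
  if (length(msg)) msg else TRUE
})

#' LabeledRecord: a synthetic snoRNA with planted ground truth
#'
#' @slot record a [SnoRNARecord-class].
#' @slot truth list holding planted box coordinates, planted [FeatureSet-class],
#'   planted category, and matched substrate sequences with planted target
#'   positions.
#' @exportClass LabeledRecord
setClass("LabeledRecord", representation(record = "SnoRNARecord", truth = "list"))

#' GuideDuplex: a guide-substrate antiparallel duplex
#'
#' @slot snornaId,boxKind identity of the guide (box \code{"D"} or
#'   \code{"Dprime"}).
#' @slot guideRange,substrateRange 1-based inclusive ranges (length-2 integer).
#' @slot substrateId character(1).
#' @slot length number of paired nucleotides.
#' @slot pairMap integer matrix with columns \code{guide}, \code{substrate};
#'   guide indices descend along ascending substrate indices (antiparallel).
#' @slot nWC number of Watson-Crick (non-wobble) pairs.
#' @exportClass GuideDuplex
setClass("GuideDuplex",
         representation(snornaId = "character", boxKind = "character",
                        guideRange = "integer", substrateId = "character",
                        substrateRange = "integer", length = "integer",
                        pairMap = "matrix", nWC = "integer"))

setValidity("GuideDuplex", function(object) {
  msg <- character()
  if (nrow(object@pairMap) != object@length)
    msg <- c(msg, "length must equal the number of rows of pairMap")
  g <- object@pairMap[, "guide"]; s <- object@pairMap[, "substrate"]
  if (object@length > 1L && (any(diff(g) != -1L) || any(diff(s) != 1L)))
    msg <- c(msg, "pairMap must be contiguous and antiparallel")
  if (length(msg)) msg else TRUE
})
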