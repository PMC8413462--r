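# K-turn coordinate frame and feature evaluation.
#
# Slot naming: the box C'-like 7-mer window occupies, 5' to 3', positions
# L2, L3, b1, b2, b3, b4, b5 (the b strand of stem II); the box D'-like 4-mer
# window occupies n4, n3, n2, n1 (the n strand, antiparallel: ascending b index
# pairs descending sequence position on the n side). Stem I pairs -1 and -2 sit
# outside the windows: minus1_b/minus2_b immediately 5' of L1 (itself 5' of the
# C' window) and minus1_n/minus2_n immediately 3' of the D' window. n5 stacks
# 5' of the D' window. Under this map the consensus RUGAUGA / CUGA placement
# yields the tandem sheared pairs (b1,n1)=(G,A) and (b2,n2)=(A,G) flanking the
# kink, plus (b3,n3)=(U,U) and (b4,n4)=(G,C).

.PAIR_TYPES <- c("WC", "WOBBLE", "SHEARED_GA", "SHEARED_AG", "OTHER", "ABSENT")

#' Classify an ordered nucleotide pair
#'
#' Total function of an ordered (b-side, n-side) nucleotide pair. \code{N} and
#' absent positions (\code{NA}) never count as pairing partners.
#'
#' @param b,n single nucleotides in \code{A,C,G,U,N} or \code{NA} (absent).
#' @return one of \code{"WC"}, \code{"WOBBLE"}, \code{"SHEARED_GA"},
#'   \code{"SHEARED_AG"}, \code{"OTHER"}, \code{"ABSENT"}.
#' @examples
#' classifyPair("G", "C")  # "WC"
#' classifyPair("G", "U")  # "WOBBLE"
#' classifyPair("G", "A")  # "SHEARED_GA"
#' @export
classifyPair <- function(b, n) {
  if (is.na(b) || is.na(n) || b == "N" || n == "N") return("ABSENT")
  key <- paste0(b, n)
  switch(key,
         GC = , CG = , AU = , UA = "WC",
         GU = , UG = "WOBBLE",
         GA = "SHEARED_GA",
         AG = "SHEARED_AG",
         "OTHER")
}

#' Build a k-turn coordinate frame
#'
#' Places the k-turn slot map onto a sequence for a box C'-like 7-mer window
#' starting at \code{cStart} and a box D'-like 4-mer window starting at
#' \code{dStart} (both 1-based). For \code{motifKind = "internal"} the D'
#' window must lie entirely 5' of the C' window, with the two stem I positions
#' 3' of the D' window (\code{dStart+4}, \code{dStart+5}) clear of the C'
#' window; for \code{"terminal"} (box C/D) the C window lies 5' of the D
#' window. Stem I / loop slots outside the sequence are flagged absent; the
#' stem II core (b1..b5, n1..n4) must be inside.
#'
#' @param seq RNA string.
#' @param cStart,dStart 1-based starts of the 7-mer and 4-mer windows.
#' @param motifKind \code{"internal"} or \code{"terminal"}.
#' @return a [KTurnFrame-class].
#' @export
buildKTurnFrame <- function(seq, cStart, dStart,
                            motifKind = c("internal", "terminal")) {
  motifKind <- match.arg(motifKind)
  len <- nchar(seq)
  cStart <- as.integer(cStart); dStart <- as.integer(dStart)
  if (cStart < 1L || cStart + 6L > len)
    stop("box C'-like 7-mer window out of range", call. = FALSE)
  if (dStart < 1L || dStart + 3L > len)
    stop("box D'-like 4-mer window out of range", call. = FALSE)
  if (motifKind == "internal") {
    if (dStart + 5L >= cStart)
      stop("D' window (plus its two stem I positions) must lie entirely 5' of the C' window",
           call. = FALSE)
  } else {
    if (cStart + 6L >= dStart)
      stop("terminal box C window must lie entirely 5' of the box D window",
           call. = FALSE)
  }
  pos <- c(minus2_b = cStart - 3L, minus1_b = cStart - 2L, L1 = cStart - 1L,
           L2 = cStart, L3 = cStart + 1L,
           b1 = cStart + 2L, b2 = cStart + 3L, b3 = cStart + 4L,
           b4 = cStart + 5L, b5 = cStart + 6L,
           n5 = dStart - 1L, n4 = dStart, n3 = dStart + 1L,
           n2 = dStart + 2L, n1 = dStart + 3L,
           minus1_n = dStart + 4L, minus2_n = dStart + 5L)
  absent <- pos < 1L | pos > len
  if (any(absent[.CORE_SLOTS]))
    stop("stem II core slots out of sequence range", call. = FALSE)
  new("KTurnFrame", positions = pos, absent = absent,
      motifKind = motifKind, seqLength = as.integer(len))
}

#' @describeIn buildKTurnFrame accessor for the named position map.
#' @param frame a KTurnFrame.
#' @export
framePositions <- function(frame) frame@positions

#' @describeIn buildKTurnFrame nucleotide at a named frame slot (\code{NA} if
#'   absent).
#' @param slot slot name, e.g. \code{"b1"}, \code{"minus1_n"}.
#' @export
frameNucleotide <- function(frame, seq, slot) {
  if (frame@absent[[slot]]) return(NA_character_)
  p <- frame@positions[[slot]]
  substr(seq, p, p)
}

#' Evaluate the k-turn features of a frame placement
#'
#' Computes the feature set the classification rules consume: the tandem
#' sheared pairs are nucleotide-identity checks (exactly G with A / A with G);
#' a stem I pair counts as intact when it is Watson-Crick or G:U wobble (the
#' wobble admission reflects stems that open with a G:U pair); k-loop is
#' declared only when both the -1 and -2 pairs fail or are absent, a failed
#' -1 with an intact -2 being a broken stem rather than a loop.
#'
#' @param frame a [KTurnFrame-class].
#' @param seq the sequence the frame was built on.
#' @return a [FeatureSet-class].
#' @export
evaluateFeatures <- function(frame, seq) {
  if (nchar(seq) != frame@seqLength)
    stop("sequence length does not match the frame", call. = FALSE)
  nt <- function(slot) frameNucleotide(frame, seq, slot)
  s1 <- identical(nt("b1"), "G") && identical(nt("n1"), "A")
  s2 <- identical(nt("b2"), "A") && identical(nt("n2"), "G")
  m1 <- classifyPair(nt("minus1_b"), nt("minus1_n")) %in% c("WC", "WOBBLE")
  m2 <- classifyPair(nt("minus2_b"), nt("minus2_n")) %in% c("WC", "WOBBLE")
  cwin <- substr(seq, frame@positions[["L2"]], frame@positions[["b5"]])
  dwin <- substr(seq, frame@positions[["n4"]], frame@positions[["n1"]])
  new("FeatureSet",
      hasSheared1 = s1, hasSheared2 = s2,
      stem1Minus1 = m1, stem1Minus2 = m2,
      isKloop = !m1 && !m2,
      cprimeConsensus = grepl("^[AG]UGAUGA$", cwin),
      dprimeConsensus = identical(dwin, "CUGA"),
      stem2Score = scoreStemII(cwin, dwin))
}

#' Construct a FeatureSet directly
#'
#' Convenience constructor used for feature sets known from experiment rather
#' than derived from a sequence (e.g. the construct panel).
#'
#' @param hasSheared1,hasSheared2,stem1Minus1,stem1Minus2 logicals.
#' @param cprimeConsensus,dprimeConsensus logicals.
#' @param stem2Score integer 0..4.
#' @param isKloop logical; default is derived from the stem I flags.
#' @return a [FeatureSet-class].
#' @export
FeatureSet <- function(hasSheared1, hasSheared2, stem1Minus1, stem1Minus2,
                       cprimeConsensus = FALSE, dprimeConsensus = FALSE,
                       stem2Score = 0L, isKloop = !stem1Minus1 && !stem1Minus2) {
  new("FeatureSet", hasSheared1 = hasSheared1, hasSheared2 = hasSheared2,
      stem1Minus1 = stem1Minus1, stem1Minus2 = stem1Minus2, isKloop = isKloop,
      cprimeConsensus = cprimeConsensus, dprimeConsensus = dprimeConsensus,
      stem2Score = as.integer(stem2Score))
}

#' @describeIn FeatureSet feature set as a one-row data.frame.
#' @param x a FeatureSet.
#' @export
featureTable <- function(x) {
  data.frame(has_sheared_1 = x@hasSheared1, has_sheared_2 = x@hasSheared2,
             stem1_minus1 = x@stem1Minus1, stem1_minus2 = x@stem1Minus2,
             is_kloop = x@isKloop, cprime_consensus = x@cprimeConsensus,
             dprime_consensus = x@dprimeConsensus, stem2_score = x@stem2Score,
             stringsAsFactors = FALSE)
}

setMethod("show", "KTurnFrame", function(object) {
  cat(sprintf("KTurnFrame (%s motif) on a %d-nt sequence\n",
              object@motifKind, object@seqLength))
  shown <- object@positions
  shown[object@absent] <- NA_integer_
  print(shown)
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:\n")
  df <- featureTable(object)
  cat(paste0("  ", names(df), ": ", unlist(lapply(df, as.character)),
             collapse = "\n"), "\n")
})
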