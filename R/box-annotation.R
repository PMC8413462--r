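# Box C/D/C'/D' annotation.
#
# Rules: box C matches the degenerate consensus RUGAUGA (R = A or G) and must
# start within a few nucleotides of the 5' end; box D and D' are exact CUGA
# matches (D boxes are treated as strictly conserved); box C' is selected
# among all admissible 7-mer windows between box D' and the guide upstream of
# box D by maximizing the number of stem II pairs with canonical identity.

.BOXC_CONSENSUS <- c("R", "U", "G", "A", "U", "G", "A")

.newBox <- function(kind, start, windowSeq, mismatches = 0L, score = NA_integer_,
                    rank = 1L) {
  width <- if (kind %in% c("C", "Cprime")) 7L else 4L
  new("BoxAnnotation", boxKind = kind, start = as.integer(start),
      end = as.integer(start + width - 1L), windowSeq = windowSeq,
      mismatches = as.integer(mismatches), score = as.integer(score),
      selectionRank = as.integer(rank))
}

#' @describeIn findBoxC accessors for box coordinates (1-based inclusive).
#' @param x a BoxAnnotation.
#' @export
boxStart <- function(x) x@start

#' @describeIn findBoxC end coordinate accessor.
#' @export
boxEnd <- function(x) x@end

#' @describeIn findBoxC box kind accessor.
#' @export
boxKind <- function(x) x@boxKind

.mismatchesToBoxC <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  ok <- chars == .BOXC_CONSENSUS
  ok[1L] <- chars[1L] %in% c("A", "G")
  sum(!ok)
}

#' Find box C at the 5' end
#'
#' Scans the 7-mer windows starting at offsets \code{0..maxStart} from the 5'
#' end against the RUGAUGA consensus and returns the window with the fewest
#' mismatches, provided it does not exceed \code{maxMismatch}; ties are broken
#' by the smaller start.
#'
#' @param rec a [SnoRNARecord-class].
#' @param maxStart maximum 0-based offset of the window from the 5' end
#'   (default 5: the box must start within 5 nt of the 5' end).
#' @param maxMismatch maximum mismatches to RUGAUGA (default 1).
#' @return a [BoxAnnotation-class], or \code{NULL} if no window qualifies.
#' @export
findBoxC <- function(rec, maxStart = 5L, maxMismatch = 1L) {
  seq <- snoSeq(rec)
  if (nchar(seq) < 7L) return(NULL)
  starts <- seq_len(min(maxStart + 1L, nchar(seq) - 6L))
  mm <- vapply(starts, function(s) .mismatchesToBoxC(substr(seq, s, s + 6L)),
               integer(1))
  ok <- which(mm <= maxMismatch)
  if (!length(ok)) return(NULL)
  best <- ok[which.min(mm[ok])]   # ties: smaller start (which.min is first)
  .newBox("C", starts[best], substr(seq, starts[best], starts[best] + 6L),
          mismatches = mm[best])
}

#' Find box D / D' candidates
#'
#' Returns all exact CUGA occurrences within \code{searchRegion}. When the
#' guide position paired with the known target nucleotide is supplied, only the
#' occurrence starting exactly five nucleotides downstream of it
#' (\code{start == guidePos + 5}, 1-based) is kept. For box D with no target
#' information the default region is the final 15 nt and candidates are ranked
#' 3'-most first; D' candidates are ranked 5'-most first.
#'
#' @param rec a [SnoRNARecord-class].
#' @param kind \code{"D"} or \code{"Dprime"}.
#' @param searchRegion length-2 integer range (1-based inclusive), or
#'   \code{NULL} for the default.
#' @param knownTargetGuidePos optional 1-based snoRNA position of the guide
#'   nucleotide paired with the target.
#' @return list of [BoxAnnotation-class] (possibly empty), ranked.
#' @export
findBoxD <- function(rec, kind = c("D", "Dprime"), searchRegion = NULL,
                     knownTargetGuidePos = NULL) {
  kind <- match.arg(kind)
  seq <- snoSeq(rec)
  len <- nchar(seq)
  if (is.null(searchRegion)) {
    if (kind == "D") searchRegion <- c(max(1L, len - 14L), len)
    else searchRegion <- c(1L, len)
  }
  lo <- max(1L, as.integer(searchRegion[1L]))
  hi <- min(len, as.integer(searchRegion[2L]))
  if (lo > hi) stop("empty search region", call. = FALSE)
  region <- substr(seq, lo, hi)
  starts <- integer()
  if (nchar(region) >= 4L) {
    m <- gregexpr("(?=CUGA)", region, perl = TRUE)[[1L]]
    if (m[1L] != -1L) starts <- as.integer(m) + lo - 1L
  }
  if (!is.null(knownTargetGuidePos))
    starts <- starts[starts == knownTargetGuidePos + 5L]
  if (!length(starts)) return(list())
  if (kind == "D") starts <- sort(starts, decreasing = TRUE)
  lapply(seq_along(starts), function(i)
    .newBox(kind, starts[i], substr(seq, starts[i], starts[i] + 3L),
            rank = i))
}

#' Score stem II of a C'/D' window pair
#'
#' Counts how many of the four stem II pairs have canonical nucleotide
#' identity, pairing the two windows antiparallel: (b1,n1)=(G,A),
#' (b2,n2)=(A,G), (b3,n3)=(U,U), (b4,n4)=(G,C), where b1..b4 are positions
#' 3..6 of the 7-mer and n1..n4 are positions 4..1 of the 4-mer.
#'
#' @param cprimeWindow 7-mer box C'-like window.
#' @param dprimeWindow 4-mer box D'-like window.
#' @return integer in 0..4.
#' @examples
#' scoreStemII("AUGAUGA", "CUGA")  # 4: consensus vs consensus
#' scoreStemII("UACAUGU", "CUGA")  # 3
#' @export
scoreStemII <- function(cprimeWindow, dprimeWindow) {
  if (nchar(cprimeWindow) != 7L) stop("box C'-like window must be 7 nt", call. = FALSE)
  if (nchar(dprimeWindow) != 4L) stop("box D'-like window must be 4 nt", call. = FALSE)
  b <- strsplit(cprimeWindow, "", fixed = TRUE)[[1L]][3:6]
  n <- rev(strsplit(dprimeWindow, "", fixed = TRUE)[[1L]])  # n1, n2, n3, n4
  canonical <- matrix(c("G", "A", "A", "G", "U", "U", "G", "C"),
                      ncol = 2L, byrow = TRUE)
  sum(b == canonical[, 1L] & n == canonical[, 2L])
}

#' Select box C' by stem II maximization
#'
#' Enumerates every admissible 7-mer window between the box D' motif and the
#' guide region upstream of box D (window start at least three positions past
#' the D' end, leaving its two stem I positions free; window end at least
#' \code{minGapToD} nucleotides before box D, reserving a minimal guide) and
#' returns the window maximizing [scoreStemII()] against the D' window. Ties
#' are broken by fewer mismatches to RUGAUGA, then by the smaller start.
#'
#' @param rec a [SnoRNARecord-class].
#' @param dprime,boxd [BoxAnnotation-class] for box D' and box D.
#' @param minGapToD minimum number of nucleotides between the C' window end
#'   and the box D start (default 6).
#' @return a [BoxAnnotation-class] (with \code{score}), or \code{NULL} if the
#'   interval admits no window.
#' @export
findBoxCprime <- function(rec, dprime, boxd, minGapToD = 6L) {
  stopifnot(boxEnd(dprime) < boxStart(boxd))
  seq <- snoSeq(rec)
  lo <- boxEnd(dprime) + 3L
  hi <- boxStart(boxd) - minGapToD - 7L   # window end <= boxd start - minGap - 1
  if (lo > hi) return(NULL)
  starts <- lo:hi
  dwin <- dprime@windowSeq
  wins <- substring(seq, starts, starts + 6L)
  scores <- vapply(wins, scoreStemII, integer(1), dprimeWindow = dwin,
                   USE.NAMES = FALSE)
  mism <- vapply(wins, .mismatchesToBoxC, integer(1), USE.NAMES = FALSE)
  ord <- order(-scores, mism, starts)
  best <- ord[1L]
  .newBox("Cprime", starts[best], wins[best], mismatches = mism[best],
          score = scores[best])
}

#' Offset between two annotation windows
#'
#' Returns the smallest positive shift \code{s} such that the suffix
#' \code{a[s+1..]} equals the prefix \code{b[..len-s]} (the two windows tile
#' one consistent region, \code{b} displaced \code{s} nucleotides 3' of
#' \code{a}); 0 if the windows are identical; \code{NA} if no shift up to
#' \code{len - 1} works.
#'
#' @param a,b equal-length windows.
#' @return integer shift, or \code{NA}.
#' @examples
#' windowOffset("UUGAUGA", "AUGACUA")  # 3
#' @export
windowOffset <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("windows must have equal length", call. = FALSE)
  len <- nchar(a)
  if (identical(a, b)) return(0L)
  for (s in seq_len(len - 1L))
    if (substr(a, s + 1L, len) == substr(b, 1L, len - s)) return(s)
  NA_integer_
}

#' Annotate all boxes of one snoRNA
#'
#' Runs the full annotation: box C at the 5' end, box D in the 3'-terminal
#' region (3'-most CUGA first), then joint selection of the (box D', box C')
#' pair. Without target information every CUGA between box C and box D is a D'
#' candidate, and the candidate pair maximizing the stem II score is chosen
#' jointly, ties going to the 5'-most D'. When no C' window reaches a stem II
#' score of at least 1, the snoRNA is annotated as having no credible box
#' C'/D' rather than forcing a window.
#'
#' @inheritParams findBoxC
#' @inheritParams findBoxCprime
#' @return a [SnoRNAAnnotation-class].
#' @export
annotateBoxes <- function(rec, maxStart = 5L, maxMismatch = 1L, minGapToD = 6L) {
  seq <- snoSeq(rec)
  notes <- character()
  boxC <- findBoxC(rec, maxStart = maxStart, maxMismatch = maxMismatch)
  if (is.null(boxC)) notes <- c(notes, "no box C within the 5'-terminal allowance")
  dCands <- findBoxD(rec, "D")
  boxD <- if (length(dCands)) dCands[[1L]] else NULL
  if (is.null(boxD)) notes <- c(notes, "no box D (CUGA) in the 3'-terminal region")
  if (length(dCands) > 1L)
    notes <- c(notes, sprintf("box D tie-break: %d CUGA candidates in the 3' region, 3'-most selected",
                              length(dCands)))

  boxDprime <- NULL; boxCprime <- NULL
  if (!is.null(boxD)) {
    intLo <- if (is.null(boxC)) 1L else boxEnd(boxC) + 1L
    intHi <- boxStart(boxD) - 1L
    dpCands <- if (intLo + 3L <= intHi)
      findBoxD(rec, "Dprime", searchRegion = c(intLo, intHi)) else list()
    dpCands <- Filter(function(b) boxEnd(b) <= intHi, dpCands)
    if (length(dpCands)) {
      pairs <- lapply(dpCands, function(dp)
        findBoxCprime(rec, dp, boxD, minGapToD = minGapToD))
      scores <- vapply(pairs, function(cp) if (is.null(cp)) -1L else cp@score,
                       integer(1))
      if (any(scores >= 1L)) {
        best <- which.max(scores)   # ties: 5'-most D' (candidates are 5'->3')
        if (sum(scores == scores[best]) > 1L)
          notes <- c(notes, "box D'/C' tie-break: equal stem II scores, 5'-most D' selected")
        boxDprime <- dpCands[[best]]
        boxCprime <- pairs[[best]]
      } else {
        notes <- c(notes, "no credible box C'/D' (no window with stem II score >= 1)")
      }
    } else {
      notes <- c(notes, "no credible box C'/D' (no internal CUGA candidate)")
    }
  }

  internalFrame <- NULL
  if (!is.null(boxDprime) && !is.null(boxCprime))
    internalFrame <- buildKTurnFrame(seq, boxStart(boxCprime),
                                     boxStart(boxDprime), "internal")
  terminalFrame <- NULL
  if (!is.null(boxC) && !is.null(boxD) && boxEnd(boxC) + 6L < boxStart(boxD))
    terminalFrame <- buildKTurnFrame(seq, boxStart(boxC), boxStart(boxD),
                                     "terminal")
  new("SnoRNAAnnotation", snornaId = snoId(rec), boxC = boxC,
      boxDprime = boxDprime, boxCprime = boxCprime, boxD = boxD,
      internalFrame = internalFrame, terminalFrame = terminalFrame,
      notes = notes)
}

#' Annotation results as a coordinate table
#'
#' One row per annotated box. Coordinates are 1-based inclusive.
#'
#' @param annotations list of [SnoRNAAnnotation-class].
#' @return data.frame with columns snoRNA_id, box_kind, start, end, window,
#'   mismatches, stem2_score.
#' @export
annotationTable <- function(annotations) {
  rows <- list()
  for (ann in annotations) {
    for (slot in c("boxC", "boxDprime", "boxCprime", "boxD")) {
      b <- slot(ann, slot)
      if (is.null(b)) next
      rows[[length(rows) + 1L]] <-
        data.frame(snoRNA_id = ann@snornaId, box_kind = boxKind(b),
                   start = boxStart(b), end = boxEnd(b), window = b@windowSeq,
                   mismatches = b@mismatches, stem2_score = b@score,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(snoRNA_id = character(), box_kind = character(),
                      start = integer(), end = integer(), window = character(),
                      mismatches = integer(), stem2_score = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Export box annotations as BED
#'
#' Writes a BED6 track of box coordinates (snoRNA ids as sequence names; BED
#' is 0-based half-open by convention, conversion handled by the exporter).
#' The score column carries the stem II score where defined.
#'
#' @param annotations list of [SnoRNAAnnotation-class].
#' @param path output BED file.
#' @param seqLengths named integer vector of snoRNA lengths.
#' @return \code{path}, invisibly.
#' @export
writeBoxBed <- function(annotations, path, seqLengths) {
  tab <- annotationTable(annotations)
  if (!nrow(tab)) stop("nothing to export", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$snoRNA_id,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = "+",
    name = tab$box_kind,
    score = ifelse(is.na(tab$stem2_score), 0L, tab$stem2_score))
  GenomeInfoDb::seqlengths(gr) <- seqLengths[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

setMethod("show", "BoxAnnotation", function(object) {
  cat(sprintf("BoxAnnotation %s [%d-%d] %s (mismatches=%d%s)\n",
              object@boxKind, object@start, object@end, object@windowSeq,
              object@mismatches,
              if (!is.na(object@score)) sprintf(", stem II score=%d", object@score)
              else ""))
})

setMethod("show", "SnoRNAAnnotation", function(object) {
  cat(sprintf("SnoRNAAnnotation for '%s'\n", object@snornaId))
  for (slot in c("boxC", "boxDprime", "boxCprime", "boxD")) {
    b <- slot(object, slot)
    if (is.null(b)) cat(sprintf("  %-9s absent\n", sub("box", "", slot)))
    else cat(sprintf("  %-9s [%d-%d] %s\n", boxKind(b), boxStart(b), boxEnd(b),
                     b@windowSeq))
  }
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
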