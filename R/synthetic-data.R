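# Labelled synthetic snoRNA benchmark generator.
#
# Emulated architecture (5' to 3'):
#   [tail] boxC(7) [guide1] boxD'(4) [stemI n-side: -1,-2] [spacer]
#   [stemI b-side: -2,-1] [L1] boxC'(7) [guide2] boxD(4) [tail]
# Guides are exact reverse complements of windows in matched substrate RNAs;
# the methylation target is planted at the substrate position paired with the
# fifth guide nucleotide upstream of the box. Stem II and stem I pairs of the
# internal motif are set to realize a requested functional category. After
# planting, every record is rescanned and regenerated if annotation would not
# recover the planted placement unambiguously, so truth labels are exact.

.COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

.revcomp <- function(x) {
  chars <- rev(strsplit(x, "", fixed = TRUE)[[1L]])
  paste0(.COMPLEMENT[chars], collapse = "")
}

.randSeq <- function(n) paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                               collapse = "")

# Nucleotide that forms neither a WC nor a wobble nor a sheared pair with x.
.nonPairing <- function(x) if (x == "G") "G" else "C"

#' Largest-remainder apportionment of category proportions
#'
#' Converts proportions to integer counts summing to \code{n}: floor the
#' quotas, then distribute the remaining units to the largest fractional
#' remainders (ties by category order). Deterministic.
#'
#' @param proportions named numeric vector summing to 1.
#' @param n total count.
#' @return named integer vector summing to \code{n}.
#' @export
apportionCounts <- function(proportions, n) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1", call. = FALSE)
  quota <- proportions * n
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- quota - counts
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# Default category mix: the composition reported for the 43 yeast
# methylation-guide snoRNAs (2 canonical, 6 near-canonical, 18 tandem without
# stem I, 17 missing a sheared pair).
.DEFAULT_MIX <- c(CANONICAL = 2, FUNCTIONAL_NONCANONICAL = 6,
                  TANDEM_NO_STEM1 = 18, MISSING_SHEARED = 17, NO_MOTIF = 0) / 43

.buildOne <- function(id, category, guideLenD, guideLenDprime, spacerLen,
                      kloopFraction, flankLen = 2L) {
  tail5 <- sample(0:3, 1L)
  tail3 <- sample(0:3, 1L)
  boxC <- paste0(sample(c("A", "G"), 1L), "UGAUGA")
  guide1 <- .randSeq(guideLenDprime)
  guide2 <- .randSeq(guideLenD)
  spacer <- .randSeq(spacerLen)
  L1 <- sample(c("A", "C", "G", "U"), 1L)

  # internal C'/D' windows and stem I per category
  cwin <- paste0(sample(c("A", "G"), 1L), "UGAUGA")
  dwin <- "CUGA"
  breakConsensus <- function(w) {          # mutate L3 (pos 2): no pair touched
    substr(w, 2L, 2L) <- sample(c("A", "C", "G"), 1L); w
  }
  stem1Intact <- c(TRUE, TRUE)             # (-1, -2)
  if (category == "FUNCTIONAL_NONCANONICAL") {
    cwin <- breakConsensus(cwin)
  } else if (category == "TANDEM_NO_STEM1") {
    cwin <- breakConsensus(cwin)
    stem1Intact[1L] <- FALSE
    if (stats::runif(1) < kloopFraction) stem1Intact[2L] <- FALSE
  } else if (category == "MISSING_SHEARED") {
    # natives of this class are non-consensus throughout, so break the
    # consensus as well as one sheared pair
    cwin <- breakConsensus(cwin)
    if (stats::runif(1) < 0.5) substr(cwin, 3L, 3L) <- "C"   # break b1 (1b.1n)
    else substr(cwin, 4L, 4L) <- "C"                         # break b2 (2b.2n)
  }

  # stem I nucleotides: n side follows box D', b side precedes L1 + box C'
  n1n <- sample(c("A", "C", "G", "U"), 1L)
  n2n <- sample(c("A", "C", "G", "U"), 1L)
  b1 <- if (stem1Intact[1L]) .COMPLEMENT[[n1n]] else .nonPairing(n1n)
  b2 <- if (stem1Intact[2L]) .COMPLEMENT[[n2n]] else .nonPairing(n2n)

  if (category == "NO_MOTIF") {
    interior <- .randSeq(guideLenDprime + 4L + 2L + spacerLen + 3L + 7L)
    seq <- paste0(.randSeq(tail5), boxC, interior, guide2, "CUGA",
                  .randSeq(tail3))
    cStart <- NA_integer_; dpStart <- NA_integer_
  } else {
    seq <- paste0(.randSeq(tail5), boxC, guide1, dwin, n1n, n2n, spacer,
                  b2, b1, L1, cwin, guide2, "CUGA", .randSeq(tail3))
    dpStart <- tail5 + 7L + guideLenDprime + 1L
    cStart <- dpStart + 4L + 2L + spacerLen + 3L
  }
  boxCStart <- tail5 + 1L
  boxDStart <- nchar(seq) - tail3 - 3L

  # matched substrates: 2-nt random flanks around the reverse complement of
  # each guide; planted target = flank + 5 (pairs guide position boxStart - 5)
  subs <- list()
  mkSub <- function(guide, name) {
    list(id = name,
         seq = paste0(.randSeq(flankLen), .revcomp(guide), .randSeq(flankLen)),
         target = flankLen + 5L)
  }
  subs$D <- mkSub(guide2, paste0(id, "_sub_D"))
  if (category != "NO_MOTIF") subs$Dprime <- mkSub(guide1, paste0(id, "_sub_Dp"))

  rec <- SnoRNARecord(id, seq, source = "synthetic")
  truth <- list(category = category,
                boxC = c(boxCStart, boxCStart + 6L),
                boxD = c(boxDStart, boxDStart + 3L),
                boxDprime = if (is.na(dpStart)) NULL else c(dpStart, dpStart + 3L),
                boxCprime = if (is.na(cStart)) NULL else c(cStart, cStart + 6L),
                substrates = subs)
  if (!is.na(cStart)) {
    frame <- buildKTurnFrame(seq, cStart, dpStart, "internal")
    truth$features <- evaluateFeatures(frame, seq)
  }
  new("LabeledRecord", record = rec, truth = truth)
}

# TRUE when annotation run on the bare sequence recovers the planted boxes and
# category, and (for motif categories) the planted placement is the unique
# stem II argmax among all candidate (D', C') placements.
.unambiguous <- function(lr, minGapToD = 6L) {
  rec <- lr@record; tr <- lr@truth
  ann <- annotateBoxes(rec, minGapToD = minGapToD)
  if (is.null(ann@boxC) || boxStart(ann@boxC) != tr$boxC[1L]) return(FALSE)
  if (is.null(ann@boxD) || boxStart(ann@boxD) != tr$boxD[1L]) return(FALSE)
  if (tr$category == "NO_MOTIF")
    return(is.null(ann@boxDprime) && is.null(ann@boxCprime))
  if (is.null(ann@boxDprime) || is.null(ann@boxCprime)) return(FALSE)
  if (boxStart(ann@boxDprime) != tr$boxDprime[1L] ||
      boxStart(ann@boxCprime) != tr$boxCprime[1L]) return(FALSE)
  cls <- classifyMotif(evaluateFeatures(ann@internalFrame, snoSeq(rec)))
  if (cls@category != tr$category) return(FALSE)
  # uniqueness: no other admissible placement ties the planted score
  seq <- snoSeq(rec)
  planted <- ann@boxCprime@score
  dpAll <- findBoxD(rec, "Dprime",
                    searchRegion = c(boxEnd(ann@boxC) + 1L,
                                     boxStart(ann@boxD) - 1L))
  dpAll <- Filter(function(b) boxEnd(b) < boxStart(ann@boxD), dpAll)
  for (dp in dpAll) {
    lo <- boxEnd(dp) + 3L
    hi <- boxStart(ann@boxD) - minGapToD - 7L
    if (lo > hi) next
    for (s in lo:hi) {
      if (boxStart(dp) == tr$boxDprime[1L] && s == tr$boxCprime[1L]) next
      if (scoreStemII(substr(seq, s, s + 6L), dp@windowSeq) >= planted)
        return(FALSE)
    }
  }
  # methylation targets must round-trip
  for (kind in names(tr$substrates)) {
    box <- if (kind == "D") ann@boxD else ann@boxDprime
    sub <- tr$substrates[[kind]]
    dx <- findGuideDuplex(rec, box, sub$seq, substrateId = sub$id)
    if (is.null(dx)) return(FALSE)
    site <- tryCatch(predictMethylationSite(dx, box, rec, sub$seq),
                     error = function(e) NA_integer_)
    if (is.na(site) || site != sub$target) return(FALSE)
  }
  TRUE
}

#' Generate labelled synthetic snoRNAs
#'
#' Generates \code{n} snoRNA-like sequences with planted box motifs realizing
#' the requested category mix, plus matched substrate RNAs with planted
#' methylation targets. Category proportions are converted to counts by
#' largest-remainder apportionment. An ambiguity guard rescans each sequence
#' and regenerates it if a spurious placement ties or beats the planted stem
#' II score, so truth labels are guaranteed recoverable. Deterministic under
#' \code{seed}.
#'
#' @param n number of records.
#' @param categoryMix named proportions over the five categories (summing
#'   to 1). The default is the composition reported for the 43 yeast
#'   methylation-guide snoRNAs.
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @param guideLenD,guideLenDprime guide lengths in nt (defaults 12; must be
#'   >= 8).
#' @param spacerLen spacer between the stem I n-side and b-side blocks
#'   (default 5).
#' @param kloopFraction fraction of TANDEM_NO_STEM1 records whose -2 pair is
#'   also broken (k-loop rather than broken stem; default 0.5).
#' @param maxTries regeneration attempts per record before erroring.
#' @return list of [LabeledRecord-class].
#' @export
simulateSnoRNAs <- function(n, categoryMix = NULL, seed = NULL,
                            guideLenD = 12L, guideLenDprime = 12L,
                            spacerLen = 5L, kloopFraction = 0.5,
                            maxTries = 100L) {
  if (guideLenD < 8L || guideLenDprime < 8L)
    stop("guide lengths must be >= 8 nt", call. = FALSE)
  if (spacerLen < 0L) stop("spacerLen must be >= 0", call. = FALSE)
  if (is.null(categoryMix)) categoryMix <- .DEFAULT_MIX
  if (!all(names(categoryMix) %in% .MOTIF_CATEGORIES))
    stop("unknown category in categoryMix", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  counts <- apportionCounts(categoryMix, n)
  cats <- rep(names(counts), counts)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("syn%04d_%s", i, tolower(cats[i]))
    for (try in seq_len(maxTries)) {
      lr <- .buildOne(id, cats[i], guideLenD, guideLenDprime, spacerLen,
                      kloopFraction)
      if (.unambiguous(lr)) break
      lr <- NULL
    }
    if (is.null(lr))
      stop("could not generate an unambiguous record for category ", cats[i],
           call. = FALSE)
    out[[i]] <- lr
  }
  out
}

#' Apply a construct-style edit to a labelled record
#'
#' Minimal nucleotide substitutions at internal-frame positions realizing the
#' mutant-construct edits: introducing the 2b.2n sheared pair, removing the -1
#' stem I pair, replacing stem I by a loop (both pairs broken), or both of the
#' first two at once. Truth labels (features, category) are updated; all other
#' positions are untouched. Inapplicable edits (the feature is already in the
#' requested state) raise an error.
#'
#' @param lr a [LabeledRecord-class] with a planted internal motif.
#' @param edit one of \code{"introduce_sheared2"}, \code{"remove_minus1"},
#'   \code{"stem1_to_loop"}, \code{"introduce_sheared2_drop_minus1"}.
#' @return the edited [LabeledRecord-class].
#' @export
applyConstructEdit <- function(lr, edit = c("introduce_sheared2",
                                            "remove_minus1", "stem1_to_loop",
                                            "introduce_sheared2_drop_minus1")) {
  edit <- match.arg(edit)
  tr <- lr@truth
  if (is.null(tr$boxCprime))
    stop("record has no planted internal motif", call. = FALSE)
  seq <- snoSeq(lr@record)
  frame <- buildKTurnFrame(seq, tr$boxCprime[1L], tr$boxDprime[1L], "internal")
  f <- evaluateFeatures(frame, seq)
  pos <- framePositions(frame)
  setNt <- function(s, slot, nt) { substr(s, pos[[slot]], pos[[slot]]) <- nt; s }
  if (edit %in% c("introduce_sheared2", "introduce_sheared2_drop_minus1")) {
    if (f@hasSheared2) stop("2b.2n sheared pair already present", call. = FALSE)
    seq <- setNt(seq, "b2", "A"); seq <- setNt(seq, "n2", "G")
  }
  if (edit %in% c("remove_minus1", "introduce_sheared2_drop_minus1")) {
    if (!f@stem1Minus1) stop("-1 stem I pair already absent", call. = FALSE)
    seq <- setNt(seq, "minus1_b",
                 .nonPairing(frameNucleotide(frame, seq, "minus1_n")))
  }
  if (edit == "stem1_to_loop") {
    if (f@isKloop) stop("stem I already replaced by a loop", call. = FALSE)
    seq <- setNt(seq, "minus1_b",
                 .nonPairing(frameNucleotide(frame, seq, "minus1_n")))
    seq <- setNt(seq, "minus2_b",
                 .nonPairing(frameNucleotide(frame, seq, "minus2_n")))
  }
  rec <- SnoRNARecord(snoId(lr@record), seq,
                      knownTargets = knownTargets(lr@record),
                      source = paste0(lr@record@source, "+", edit))
  newFeatures <- evaluateFeatures(frame, seq)
  tr$features <- newFeatures
  tr$category <- classifyMotif(newFeatures)@category
  new("LabeledRecord", record = rec, truth = tr)
}

#' Write a benchmark to disk
#'
#' Writes the snoRNA FASTA, the substrate FASTA and a truth TSV (planted
#' 1-based coordinates, category, substrate targets).
#'
#' @param labeled list of [LabeledRecord-class].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the three paths.
#' @export
writeBenchmark <- function(labeled, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(labeled, function(lr) lr@record)
  snoPath <- file.path(dir, "snornas.fasta")
  writeSnoRNAFasta(recs, snoPath)
  subs <- list(); ids <- character()
  rows <- list()
  for (lr in labeled) {
    tr <- lr@truth
    for (kind in names(tr$substrates)) {
      s <- tr$substrates[[kind]]
      subs[[s$id]] <- s$seq
    }
    fmt <- function(x) if (is.null(x)) NA_integer_ else x[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      snoRNA_id = snoId(lr@record), category = tr$category,
      boxC_start = fmt(tr$boxC), boxDprime_start = fmt(tr$boxDprime),
      boxCprime_start = fmt(tr$boxCprime), boxD_start = fmt(tr$boxD),
      target_D = tr$substrates$D$target,
      target_Dprime = if (is.null(tr$substrates$Dprime)) NA_integer_
                      else tr$substrates$Dprime$target,
      stringsAsFactors = FALSE)
  }
  subPath <- file.path(dir, "substrates.fasta")
  set <- Biostrings::RNAStringSet(unlist(subs))
  Biostrings::writeXStringSet(set, subPath)
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(do.call(rbind, rows), truthPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(snoPath, subPath, truthPath))
}

setMethod("show", "LabeledRecord", function(object) {
  cat(sprintf("LabeledRecord '%s' (planted category %s, %d nt)\n",
              snoId(object@record), object@truth$category,
              nchar(snoSeq(object@record))))
})
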