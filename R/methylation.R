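# Guide-duplex search and 2'-O-methylation target prediction.
#
# The guide sequence immediately 5' of box D (or D') base-pairs a substrate
# RNA antiparallel; the methyl group is transferred to the substrate
# nucleotide paired with the fifth guide nucleotide upstream of the box
# (snoRNA position boxStart - 5, 1-based).

.WC_PAIRS <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE)
.WOBBLE_PAIRS <- c(GU = TRUE, UG = TRUE)

.pairOK <- function(g, s, allowWobble) {
  key <- paste0(g, s)
  isTRUE(.WC_PAIRS[key]) || (allowWobble && isTRUE(.WOBBLE_PAIRS[key]))
}

#' Find the guide-substrate duplex for a box D / D' guide
#'
#' Finds the longest contiguous antiparallel duplex between the guide region
#' immediately 5' of the box (the guide side must end at \code{boxStart - 1})
#' and any substrate window. Ties are broken by more Watson-Crick (fewer
#' wobble) pairs, then by the 5'-most substrate window. Internal gaps are not
#' allowed.
#'
#' @param rec a [SnoRNARecord-class].
#' @param box a [BoxAnnotation-class] of kind D or Dprime.
#' @param substrate substrate RNA string.
#' @param substrateId identifier carried into the result.
#' @param minLen minimum duplex length (default 8); shorter best duplexes
#'   return \code{NULL}.
#' @param allowWobble allow G:U wobble pairs inside the duplex (default TRUE).
#' @return a [GuideDuplex-class], or \code{NULL}.
#' @export
findGuideDuplex <- function(rec, box, substrate, substrateId = "substrate",
                            minLen = 8L, allowWobble = TRUE) {
  stopifnot(boxKind(box) %in% c("D", "Dprime"))
  if (!nzchar(substrate)) stop("substrate must be non-empty", call. = FALSE)
  seq <- snoSeq(rec)
  gEnd <- boxStart(box) - 1L
  if (gEnd < 1L) return(NULL)
  g <- strsplit(seq, "", fixed = TRUE)[[1L]]
  s <- strsplit(substrate, "", fixed = TRUE)[[1L]]
  nS <- length(s)
  best <- NULL
  for (t in seq_len(nS)) {
    if (!.pairOK(g[gEnd], s[t], allowWobble)) next
    L <- 1L
    while (gEnd - L >= 1L && t + L <= nS &&
           .pairOK(g[gEnd - L], s[t + L], allowWobble)) L <- L + 1L
    gIdx <- gEnd - 0:(L - 1L)
    sIdx <- t + 0:(L - 1L)
    nWC <- sum(vapply(seq_len(L), function(k)
      isTRUE(.WC_PAIRS[paste0(g[gIdx[k]], s[sIdx[k]])]), logical(1)))
    cand <- list(t = t, L = L, nWC = nWC, gIdx = gIdx, sIdx = sIdx)
    if (is.null(best) || cand$L > best$L ||
        (cand$L == best$L && cand$nWC > best$nWC))
      best <- cand    # equal L and nWC keeps the earlier (5'-most) window
  }
  if (is.null(best) || best$L < minLen) return(NULL)
  new("GuideDuplex", snornaId = snoId(rec), boxKind = boxKind(box),
      guideRange = c(min(best$gIdx), max(best$gIdx)),
      substrateId = substrateId,
      substrateRange = c(min(best$sIdx), max(best$sIdx)),
      length = best$L,
      pairMap = cbind(guide = best$gIdx, substrate = best$sIdx),
      nWC = as.integer(best$nWC))
}

#' Predict the 2'-O-methylation site
#'
#' Returns the substrate position paired with the fifth snoRNA nucleotide
#' upstream of the box (guide position \code{boxStart - 5}, 1-based). By
#' default the pair at the target position must be Watson-Crick; set
#' \code{allowWobbleAtTarget = TRUE} to accept a wobble there.
#'
#' @param duplex a [GuideDuplex-class].
#' @param box the [BoxAnnotation-class] the duplex was built for.
#' @param rec the [SnoRNARecord-class] (for the target-pair identity check).
#' @param substrate the substrate string (for the target-pair identity check).
#' @param allowWobbleAtTarget logical (default FALSE).
#' @return 1-based substrate position.
#' @export
predictMethylationSite <- function(duplex, box, rec = NULL, substrate = NULL,
                                   allowWobbleAtTarget = FALSE) {
  targetGuide <- boxStart(box) - 5L
  hit <- which(duplex@pairMap[, "guide"] == targetGuide)
  if (!length(hit))
    stop("target outside duplex: guide position ", targetGuide,
         " (fifth nucleotide upstream of the box) is unpaired", call. = FALSE)
  site <- duplex@pairMap[hit, "substrate"]
  if (!allowWobbleAtTarget && !is.null(rec) && !is.null(substrate)) {
    gnt <- substr(snoSeq(rec), targetGuide, targetGuide)
    snt <- substr(substrate, site, site)
    if (isTRUE(.WOBBLE_PAIRS[paste0(gnt, snt)]))
      stop("target-paired position is a G:U wobble; ",
           "set allowWobbleAtTarget = TRUE to accept it", call. = FALSE)
  }
  as.integer(site)
}

#' Methylation-site predictions for a record set
#'
#' For each record and each annotated D/D' box, searches every substrate for
#' the best guide duplex and predicts the target site. Predictions are checked
#' against any known targets attached to the record.
#'
#' @param records list of [SnoRNARecord-class].
#' @param annotations parallel list of [SnoRNAAnnotation-class].
#' @param substrates named character vector of substrate sequences.
#' @inheritParams findGuideDuplex
#' @return data.frame: snoRNA_id, box_kind, substrate_id, site (1-based),
#'   duplex_length, known_site, consistent.
#' @export
methylationTable <- function(records, annotations, substrates, minLen = 8L,
                             allowWobble = TRUE) {
  rows <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]; ann <- annotations[[i]]
    for (slot in c("boxDprime", "boxD")) {
      box <- slot(ann, slot)
      if (is.null(box)) next
      best <- NULL; bestId <- NULL
      for (sid in names(substrates)) {
        dx <- findGuideDuplex(rec, box, substrates[[sid]], substrateId = sid,
                              minLen = minLen, allowWobble = allowWobble)
        if (!is.null(dx) && (is.null(best) || dx@length > best@length)) {
          best <- dx; bestId <- sid
        }
      }
      if (is.null(best)) next
      site <- tryCatch(predictMethylationSite(best, box, rec,
                                              substrates[[bestId]]),
                       error = function(e) NA_integer_)
      kt <- knownTargets(rec)
      kt <- kt[kt$box_kind == boxKind(box) & kt$substrate_id == bestId, ,
               drop = FALSE]
      known <- if (nrow(kt)) kt$position[1L] else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        snoRNA_id = snoId(rec), box_kind = boxKind(box), substrate_id = bestId,
        site = site, duplex_length = best@length, known_site = known,
        consistent = if (is.na(known) || is.na(site)) NA else site == known,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(snoRNA_id = character(), box_kind = character(),
                      substrate_id = character(), site = integer(),
                      duplex_length = integer(), known_site = integer(),
                      consistent = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

setMethod("show", "GuideDuplex", function(object) {
  cat(sprintf("GuideDuplex '%s' box %s: guide %d-%d <-> %s %d-%d (%d bp, %d WC)\n",
              object@snornaId, object@boxKind, object@guideRange[1L],
              object@guideRange[2L], object@substrateId,
              object@substrateRange[1L], object@substrateRange[2L],
              object@length, object@nWC))
})
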