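# Functional classification of box C'/D' (and box C/D) motifs.
#
# The functionality criteria: a k-turn recognizable by the eukaryotic protein
# Snu13 requires the 1n-1b A:G sheared pair, the 2n-2b G:A sheared pair, and
# an intact -1 pair in stem I. The archaeal protein L7Ae is more permissive:
# the 1n-1b pair together with either an intact -1 pair or the 2n-2b pair
# suffices.

#' Classify a motif site from its features
#'
#' Categories: CANONICAL when both windows match the consensus;
#' FUNCTIONAL_NONCANONICAL when the tandem sheared pairs and the -1 stem I
#' pair are all present; TANDEM_NO_STEM1 when only the tandem sheared pairs
#' are present; MISSING_SHEARED otherwise. A site whose annotation failed is
#' NO_MOTIF (see [classifyRecords()]). Functional means CANONICAL or
#' FUNCTIONAL_NONCANONICAL.
#'
#' @param features a [FeatureSet-class].
#' @param snornaId,site identifiers carried into the result.
#' @return a [MotifClassification-class].
#' @export
classifyMotif <- function(features, snornaId = "?", site = "internal") {
  ev <- character()
  f <- features
  if (f@cprimeConsensus && f@dprimeConsensus) {
    cat. <- "CANONICAL"
    ev <- "both windows match the consensus (RUGAUGA / CUGA)"
  } else if (f@hasSheared1 && f@hasSheared2 && f@stem1Minus1) {
    cat. <- "FUNCTIONAL_NONCANONICAL"
    ev <- "tandem sheared pairs present and -1 stem I pair intact"
  } else if (f@hasSheared1 && f@hasSheared2) {
    cat. <- "TANDEM_NO_STEM1"
    ev <- "tandem sheared pairs present but -1 stem I pair missing"
  } else {
    cat. <- "MISSING_SHEARED"
    ev <- sprintf("sheared pair missing (1b.1n %s, 2b.2n %s)",
                  if (f@hasSheared1) "present" else "absent",
                  if (f@hasSheared2) "present" else "absent")
  }
  new("MotifClassification", snornaId = snornaId, site = site, category = cat.,
      functional = cat. %in% c("CANONICAL", "FUNCTIONAL_NONCANONICAL"),
      features = features, evidence = ev)
}

.noMotifClassification <- function(snornaId, site = "internal",
                                   evidence = "no credible box C'/D' annotation") {
  new("MotifClassification", snornaId = snornaId, site = site,
      category = "NO_MOTIF", functional = FALSE, features = NULL,
      evidence = evidence)
}

#' Predict Snu13 recognizability
#'
#' BINDER when the three required features (both sheared pairs and the intact
#' -1 stem I pair) hold and the stem II identity score is maximal; WEAK when
#' the three features hold but stem II deviates from the canonical identities
#' (the criteria are necessary, not sufficient, for strong binding);
#' NONBINDER otherwise.
#'
#' @param features a [FeatureSet-class].
#' @return \code{"BINDER"}, \code{"WEAK"} or \code{"NONBINDER"}.
#' @export
predictSnu13Binding <- function(features) {
  f <- features
  if (f@hasSheared1 && f@hasSheared2 && f@stem1Minus1) {
    if (f@stem2Score < 4L) "WEAK" else "BINDER"
  } else "NONBINDER"
}

#' Predict L7Ae recognizability
#'
#' BINDER when the 1n-1b sheared pair is present together with either an
#' intact -1 stem I pair or the 2n-2b sheared pair; WEAK for the k-loop case
#' carrying only the 1n-1b pair (fast-dissociating, smearing); NONBINDER
#' otherwise.
#'
#' @param features a [FeatureSet-class].
#' @return \code{"BINDER"}, \code{"WEAK"} or \code{"NONBINDER"}.
#' @export
predictL7AeBinding <- function(features) {
  f <- features
  if (f@hasSheared1 && (f@stem1Minus1 || f@hasSheared2)) return("BINDER")
  if (f@hasSheared1 && f@isKloop && !f@hasSheared2) return("WEAK")
  "NONBINDER"
}

#' Classify a set of snoRNA records end to end
#'
#' Annotates each record ([annotateBoxes()]), evaluates the internal frame
#' features and classifies the internal box C'/D' site; records without a
#' credible internal motif are NO_MOTIF.
#'
#' @param records list of [SnoRNARecord-class].
#' @inheritParams annotateBoxes
#' @param annotations optional precomputed list of [SnoRNAAnnotation-class].
#' @return list of [MotifClassification-class] (internal site, one per record).
#' @export
classifyRecords <- function(records, maxStart = 5L, maxMismatch = 1L,
                            minGapToD = 6L, annotations = NULL) {
  if (is.null(annotations))
    annotations <- lapply(records, annotateBoxes, maxStart = maxStart,
                          maxMismatch = maxMismatch, minGapToD = minGapToD)
  mapply(function(rec, ann) {
    if (is.null(ann@internalFrame))
      return(.noMotifClassification(snoId(rec)))
    classifyMotif(evaluateFeatures(ann@internalFrame, snoSeq(rec)),
                  snornaId = snoId(rec), site = "internal")
  }, records, annotations, SIMPLIFY = FALSE)
}

#' Census over motif classifications
#'
#' Counts categories and computes the percentage of non-functional motifs,
#' \code{100 * (nTotal - nCanonical - nFunctionalNoncanonical) / nTotal}.
#' NO_MOTIF records count as non-functional.
#'
#' @param classifications non-empty list of [MotifClassification-class].
#' @return a [CensusReport-class].
#' @export
census <- function(classifications) {
  if (!length(classifications)) stop("empty classification list", call. = FALSE)
  cats <- vapply(classifications, function(x) x@category, character(1))
  n <- length(cats)
  cnt <- function(k) sum(cats == k)
  nc <- cnt("CANONICAL"); nf <- cnt("FUNCTIONAL_NONCANONICAL")
  new("CensusReport", nTotal = as.integer(n), nCanonical = as.integer(nc),
      nFunctionalNoncanonical = as.integer(nf),
      nTandemNoStem1 = as.integer(cnt("TANDEM_NO_STEM1")),
      nMissingSheared = as.integer(cnt("MISSING_SHEARED")),
      nNoMotif = as.integer(cnt("NO_MOTIF")),
      fractionNonfunctional = 100 * (n - nc - nf) / n)
}

#' @describeIn census census as a plain list (for JSON serialization).
#' @param report a CensusReport.
#' @export
censusAsList <- function(report) {
  list(n_total = report@nTotal,
       n_canonical = report@nCanonical,
       n_functional_noncanonical = report@nFunctionalNoncanonical,
       n_tandem_no_stem1 = report@nTandemNoStem1,
       n_missing_sheared = report@nMissingSheared,
       n_no_motif = report@nNoMotif,
       fraction_nonfunctional = report@fractionNonfunctional)
}

#' Upper bound on K_D from a saturating EMSA titration
#'
#' When an RNA is fully shifted at a 1:1 protein:RNA ratio, the dissociation
#' constant is at least one order of magnitude below the total RNA
#' concentration; the bound returned is \code{rnaTotal_uM / 10}, in nM.
#'
#' @param rnaTotal_uM total RNA concentration of the assay, in uM (> 0).
#' @return an [AffinityBound-class] (upper bound, nM).
#' @examples
#' kdUpperBound(2)  # 200 nM
#' @export
kdUpperBound <- function(rnaTotal_uM) {
  if (!is.numeric(rnaTotal_uM) || length(rnaTotal_uM) != 1L || rnaTotal_uM <= 0)
    stop("total RNA concentration must be a single positive number (uM)",
         call. = FALSE)
  new("AffinityBound", direction = "upper",
      value = rnaTotal_uM / 10 * 1000,   # uM -> nM
      basis = "saturating_ratio", rnaTotal = rnaTotal_uM)
}

#' @describeIn kdUpperBound numeric bound value in nM.
#' @param bound an AffinityBound.
#' @export
boundValue <- function(bound) bound@value

#' Classification results as a table
#'
#' @param classifications list of [MotifClassification-class].
#' @return data.frame, one row per classification, with feature columns and
#'   the predicted Snu13/L7Ae binding tiers.
#' @export
classificationTable <- function(classifications) {
  rows <- lapply(classifications, function(x) {
    feat <- if (is.null(x@features))
      data.frame(has_sheared_1 = NA, has_sheared_2 = NA, stem1_minus1 = NA,
                 stem1_minus2 = NA, is_kloop = NA, cprime_consensus = NA,
                 dprime_consensus = NA, stem2_score = NA_integer_)
    else featureTable(x@features)
    cbind(data.frame(snoRNA_id = x@snornaId, site = x@site,
                     category = x@category, functional = x@functional,
                     stringsAsFactors = FALSE),
          feat,
          data.frame(snu13 = if (is.null(x@features)) "NONBINDER"
                     else predictSnu13Binding(x@features),
                     l7ae = if (is.null(x@features)) "NONBINDER"
                     else predictL7AeBinding(x@features),
                     evidence = paste(x@evidence, collapse = "; "),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' The box C'/D' construct panel
#'
#' Feature sets of the k-turn / k-loop constructs derived from the internal
#' motifs of yeast snoRNAs snR51, snR41 and snR54 (natives kl1 and mutant
#' series kl2-kl4), the archaeal k-loop control derived from sR26, and a
#' full-consensus k-turn control, together with the experimentally observed
#' EMSA binding tiers for L7Ae and Snu13 (NA where not established). The
#' feature sets are reconstructed from the constructs' described secondary
#' structures; they are the calibration panel for [predictSnu13Binding()] and
#' [predictL7AeBinding()].
#'
#' @return data.frame with one row per construct: feature columns plus
#'   \code{l7ae_observed} and \code{snu13_observed}.
#' @export
klPanelFeatures <- function() {
  df <- data.frame(
    construct = c("sR26-kl", "snR51-kl1", "snR51-kl2", "snR51-kl3",
                  "snR51-kl4", "snR41-kl1", "snR41-kl2", "snR54-kl1",
                  "consensus-kturn"),
    has_sheared_1    = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  FALSE, TRUE,  TRUE,  TRUE),
    has_sheared_2    = c(TRUE,  FALSE, TRUE,  FALSE, TRUE,  TRUE,  TRUE,  FALSE, TRUE),
    stem1_minus1     = c(FALSE, TRUE,  TRUE,  FALSE, FALSE, TRUE,  TRUE,  FALSE, TRUE),
    stem1_minus2     = c(FALSE, TRUE,  TRUE,  FALSE, TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    cprime_consensus = c(TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    dprime_consensus = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    stem2_score      = c(4L, 2L, 3L, 2L, 3L, 3L, 4L, 2L, 4L),
    l7ae_observed    = c("BINDER", "BINDER", "BINDER", "WEAK", "BINDER",
                         "NONBINDER", "BINDER", "NONBINDER", "BINDER"),
    snu13_observed   = c("NONBINDER", "NONBINDER", "WEAK", "NONBINDER",
                         "NONBINDER", "NONBINDER", NA, "NONBINDER", "BINDER"),
    stringsAsFactors = FALSE)
  df$is_kloop <- !df$stem1_minus1 & !df$stem1_minus2
  df
}

#' @describeIn klPanelFeatures FeatureSet for one panel row.
#' @param row one row of the panel data.frame.
#' @export
panelFeatureSet <- function(row) {
  FeatureSet(hasSheared1 = row$has_sheared_1, hasSheared2 = row$has_sheared_2,
             stem1Minus1 = row$stem1_minus1, stem1Minus2 = row$stem1_minus2,
             cprimeConsensus = row$cprime_consensus,
             dprimeConsensus = row$dprime_consensus,
             stem2Score = row$stem2_score)
}

setMethod("show", "MotifClassification", function(object) {
  cat(sprintf("MotifClassification '%s' (%s site): %s%s\n", object@snornaId,
              object@site, object@category,
              if (object@functional) " [functional]" else ""))
  if (length(object@evidence))
    cat("  evidence:", paste(object@evidence, collapse = "; "), "\n")
})

setMethod("show", "CensusReport", function(object) {
  cat(sprintf("CensusReport over %d snoRNAs\n", object@nTotal))
  cat(sprintf("  canonical:                %d\n", object@nCanonical))
  cat(sprintf("  functional noncanonical:  %d\n", object@nFunctionalNoncanonical))
  cat(sprintf("  tandem, no stem I:        %d\n", object@nTandemNoStem1))
  cat(sprintf("  missing a sheared pair:   %d\n", object@nMissingSheared))
  cat(sprintf("  no motif:                 %d\n", object@nNoMotif))
  cat(sprintf("  non-functional:           %.1f%%\n", object@fractionNonfunctional))
})

setMethod("show", "AffinityBound", function(object) {
  cat(sprintf("AffinityBound: K_D %s %.4g nM (%s, total RNA %.4g uM)\n",
              if (object@direction == "upper") "<=" else ">=",
              object@value, object@basis, object@rnaTotal))
})
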