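#' Construct a SnoRNARecord
#'
#' @param id identifier.
#' @param seq RNA sequence; normalized per \code{alphabetPolicy}.
#' @param knownTargets optional data.frame with columns \code{substrate_id},
#'   \code{position}, \code{box_kind} ("D" or "Dprime").
#' @param source free-text provenance.
#' @param alphabetPolicy \code{"coerce"} uppercases and converts T to U;
#'   \code{"strict"} rejects any character outside \code{A,C,G,U}.
#' @return a [SnoRNARecord-class].
#' @examples
#' SnoRNARecord("x", "acgt")                      # seq becomes "ACGU"
#' @export
SnoRNARecord <- function(id, seq, knownTargets = NULL, source = "",
                         alphabetPolicy = c("coerce", "strict")) {
  alphabetPolicy <- match.arg(alphabetPolicy)
  seq <- normalizeRNA(seq, alphabetPolicy, id = id)
  if (is.null(knownTargets))
    knownTargets <- data.frame(substrate_id = character(), position = integer(),
                               box_kind = character(), stringsAsFactors = FALSE)
  knownTargets$position <- as.integer(knownTargets$position)
  new("SnoRNARecord", id = as.character(id), seq = seq,
      knownTargets = knownTargets, source = as.character(source))
}

#' Normalize a sequence to the RNA alphabet
#'
#' @param seq character(1).
#' @inheritParams SnoRNARecord
#' @param id record id used in error messages.
#' @return uppercase RNA string over \code{A,C,G,U,N}.
#' @export
normalizeRNA <- function(seq, alphabetPolicy = c("coerce", "strict"), id = "?") {
  alphabetPolicy <- match.arg(alphabetPolicy)
  seq <- as.character(seq)
  if (alphabetPolicy == "strict") {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% c("A", "C", "G", "U"))
    if (length(bad))
      stop(sprintf("record '%s': illegal character '%s' at position %d under strict policy",
                   id, chars[bad[1L]], bad[1L]), call. = FALSE)
    return(seq)
  }
  seq <- toupper(seq)
  seq <- chartr("T", "U", seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .RNA_ALPHABET)
  if (length(bad))
    stop(sprintf("record '%s': character '%s' at position %d cannot be coerced to the RNA alphabet",
                 id, chars[bad[1L]], bad[1L]), call. = FALSE)
  seq
}

#' Read snoRNA records from a FASTA file
#'
#' Multi-line (wrapped) FASTA is accepted; the description after the first
#' whitespace of a header is stored as \code{source} but ignored by all logic.
#' Output order equals input order.
#'
#' @param path FASTA file (RNA or DNA alphabet).
#' @inheritParams SnoRNARecord
#' @param targets optional known-targets data.frame as returned by
#'   [readKnownTargets()]; rows are attached to records by \code{snoRNA_id}.
#' @return list of [SnoRNARecord-class].
#' @export
readSnoRNAFasta <- function(path, alphabetPolicy = c("coerce", "strict"),
                            targets = NULL) {
  alphabetPolicy <- match.arg(alphabetPolicy)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    kt <- NULL
    if (!is.null(targets)) {
      hit <- targets[targets$snoRNA_id == ids[i], , drop = FALSE]
      if (nrow(hit))
        kt <- data.frame(substrate_id = hit$substrate_id,
                         position = as.integer(hit$position),
                         box_kind = hit$box_kind, stringsAsFactors = FALSE)
    }
    out[[i]] <- SnoRNARecord(ids[i], as.character(set[[i]]), knownTargets = kt,
                             source = descs[i], alphabetPolicy = alphabetPolicy)
  }
  out
}

#' Write snoRNA records to FASTA
#'
#' @param records list of [SnoRNARecord-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSnoRNAFasta <- function(records, path) {
  seqs <- Biostrings::RNAStringSet(vapply(records, snoSeq, character(1)))
  names(seqs) <- vapply(records, snoId, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a known-targets table
#'
#' TSV with columns \code{snoRNA_id}, \code{substrate_id}, \code{position}
#' (1-based), \code{box_kind} ("D" or "Dprime").
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readKnownTargets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("snoRNA_id", "substrate_id", "position", "box_kind")
  if (!all(need %in% names(df)))
    stop("known-targets table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$position <- as.integer(df$position)
  if (any(df$position < 1L)) stop("target positions must be >= 1", call. = FALSE)
  df
}

#' @describeIn SnoRNARecord accessor for the identifier.
#' @param x a SnoRNARecord.
#' @export
snoId <- function(x) x@id

#' @describeIn SnoRNARecord accessor for the sequence string.
#' @export
snoSeq <- function(x) x@seq

#' @describeIn SnoRNARecord accessor for the known-targets table.
#' @export
knownTargets <- function(x) x@knownTargets

setMethod("show", "SnoRNARecord", function(object) {
  cat(sprintf("SnoRNARecord '%s': %d nt", object@id, nchar(object@seq)))
  if (nrow(object@knownTargets))
    cat(sprintf(", %d known target(s)", nrow(object@knownTargets)))
  cat("\n  ", substr(object@seq, 1L, 60L),
      if (nchar(object@seq) > 60L) "..." else "", "\n", sep = "")
})
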