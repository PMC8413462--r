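# Theoretical average masses of proteins, RNAs and RNP assemblies.
#
# Average (not monoisotopic) residue masses; a polymer mass is the sum of its
# residue masses plus one water (condensation chemistry). The residue tables
# are versioned constants based on IUPAC 2021 average atomic weights.

.MASS_TABLE_VERSION <- "IUPAC-2021"

.WATER <- 18.01528

# Average masses of amino acid residues (Da), i.e. the free amino acid minus water.
.AA_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

# Average masses of ribonucleotide monophosphate residues in an RNA chain (Da),
# 5'-OH convention.
.RNA_RESIDUE <- c(A = 329.2059, C = 305.1808, G = 345.2053, U = 306.1653)

# Mass added by a 5'-triphosphate relative to 5'-OH: three HPO3 groups.
.TRIPHOSPHATE <- 3 * 79.97990

#' Average mass of a protein or RNA polymer
#'
#' Sum of residue masses plus one water. For RNA, the default 5' end is a
#' hydroxyl; \code{fivePrime = "triphosphate"} adds the 5'-ppp mass
#' (~0.24 kDa), relevant for in vitro transcripts.
#'
#' @param sequence one-letter sequence (20 amino acids, or A/C/G/U).
#' @param kind \code{"protein"} or \code{"rna"}.
#' @param fivePrime \code{"OH"} or \code{"triphosphate"} (RNA only).
#' @return mass in Da.
#' @examples
#' polymerMass("GG", "protein")    # 132.12 Da
#' polymerMass("ACGU", "rna")      # 1303.78 Da
#' @export
polymerMass <- function(sequence, kind = c("protein", "rna"),
                        fivePrime = c("OH", "triphosphate")) {
  kind <- match.arg(kind)
  fivePrime <- match.arg(fivePrime)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string", call. = FALSE)
  table <- if (kind == "protein") .AA_RESIDUE else .RNA_RESIDUE
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  masses <- table[chars]
  if (anyNA(masses)) {
    bad <- which(is.na(masses))[1L]
    stop(sprintf("illegal %s residue '%s' at position %d", kind, chars[bad], bad),
         call. = FALSE)
  }
  m <- sum(masses) + .WATER
  if (kind == "rna" && fivePrime == "triphosphate") m <- m + .TRIPHOSPHATE
  m
}

#' Construct a Component with computed mass
#'
#' @param name component name.
#' @param kind \code{"protein"} or \code{"rna"}.
#' @param sequence one-letter sequence.
#' @inheritParams polymerMass
#' @return a [Component-class].
#' @export
Component <- function(name, kind = c("protein", "rna"), sequence,
                      fivePrime = c("OH", "triphosphate")) {
  kind <- match.arg(kind)
  new("Component", name = name, kind = kind, sequence = sequence,
      massTableVersion = .MASS_TABLE_VERSION,
      mass = polymerMass(sequence, kind, fivePrime))
}

#' @describeIn Component component mass in Da.
#' @param x a Component or AssemblyModel.
#' @export
componentMass <- function(x) x@mass

#' Construct an AssemblyModel
#'
#' @param name model name.
#' @param components list of [Component-class].
#' @param copies integer copy numbers (>= 1), parallel to \code{components}.
#' @return an [AssemblyModel-class] with the stoichiometric mass computed.
#' @export
AssemblyModel <- function(name, components, copies) {
  copies <- as.integer(copies)
  if (any(copies < 1L)) stop("copy numbers must be >= 1", call. = FALSE)
  mass <- sum(copies * vapply(components, componentMass, numeric(1)))
  new("AssemblyModel", name = name, components = components, copies = copies,
      mass = mass)
}

#' Mass of an assembly model
#'
#' @param model an [AssemblyModel-class].
#' @return mass in Da (report in kDa rounded to one decimal for display).
#' @export
assemblyMass <- function(model) model@mass

#' Rank stoichiometry hypotheses against an observed mass
#'
#' @param observed_kDa observed mass (e.g. from SEC-MALS), in kDa.
#' @param candidates list of [AssemblyModel-class] (>= 1).
#' @return data.frame sorted by |mass - observed| (stable: ties keep candidate
#'   order), with columns model, mass_kDa (one decimal), delta_kDa.
#' @export
rankStoichiometries <- function(observed_kDa, candidates) {
  if (!length(candidates)) stop("at least one candidate required", call. = FALSE)
  mass_kDa <- vapply(candidates, assemblyMass, numeric(1)) / 1000
  delta <- mass_kDa - observed_kDa
  ord <- order(abs(delta))   # order() is stable
  data.frame(model = vapply(candidates, function(m) m@name, character(1))[ord],
             mass_kDa = round(mass_kDa[ord], 1),
             delta_kDa = round(delta[ord], 1),
             stringsAsFactors = FALSE)
}

#' Read components and a stoichiometry configuration
#'
#' Components come from a FASTA file (protein or RNA inferred from the
#' alphabet unless given in the config); stoichiometries from a YAML/JSON
#' config mapping model names to component-name -> copy-number maps.
#'
#' @param fasta FASTA of component sequences.
#' @param configPath YAML file: top-level \code{models:}, each a named map of
#'   component name to copies; optional \code{kinds:} map of component name to
#'   "protein"/"rna".
#' @return list with elements \code{components} (named list of
#'   [Component-class]) and \code{models} (list of [AssemblyModel-class]).
#' @export
readAssemblyConfig <- function(fasta, configPath) {
  set <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(set))
  cfg <- yaml::read_yaml(configPath)
  kinds <- cfg$kinds
  comps <- list()
  for (i in seq_along(set)) {
    sq <- toupper(as.character(set[[i]]))
    kind <- if (!is.null(kinds[[ids[i]]])) kinds[[ids[i]]]
            else if (grepl("^[ACGUTN]+$", sq)) "rna" else "protein"
    if (kind == "rna") sq <- chartr("T", "U", sq)
    comps[[ids[i]]] <- Component(ids[i], kind, sq)
  }
  models <- lapply(names(cfg$models), function(mn) {
    spec <- cfg$models[[mn]]
    missing <- setdiff(names(spec), names(comps))
    if (length(missing))
      stop("model '", mn, "' references unknown component(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    AssemblyModel(mn, comps[names(spec)], unlist(spec))
  })
  list(components = comps, models = models)
}

setMethod("show", "Component", function(object) {
  cat(sprintf("Component '%s' (%s, %d residues): %.1f kDa [%s]\n",
              object@name, object@kind, nchar(object@sequence),
              object@mass / 1000, object@massTableVersion))
})

setMethod("show", "AssemblyModel", function(object) {
  cat(sprintf("AssemblyModel '%s': %.1f kDa\n", object@name, object@mass / 1000))
  for (i in seq_along(object@components))
    cat(sprintf("  %dx %s (%.1f kDa)\n", object@copies[i],
                object@components[[i]]@name,
                object@components[[i]]@mass / 1000))
})
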