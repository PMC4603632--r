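#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importClassesFrom Biostrings AAStringSet
NULL

## ---------------------------------------------------------------------------
## FamilyMSA: a gapped multiple alignment of one gene family, each row tagged
## with the species it comes from and (optionally) a paralog label.
## ---------------------------------------------------------------------------

#' Gene-family multiple sequence alignment
#'
#' An S4 container for a gapped multiple alignment of one gene family.  Rows
#' are stored as an [Biostrings::AAStringSet] (gap character `-`), and each
#' row carries a species label and an optional paralog tag, so that
#' per-species statistics (identity vectors, inter-species distances) can
#' collapse multiple paralogs of the same species.
#'
#' @slot aln [Biostrings::AAStringSet] of gapped rows, all the same width.
#' @slot species character vector, one species label per row.
#' @slot paralog character vector, one paralog tag per row (`NA` if single
#'   copy).
#' @slot family single character, the gene-family name (free text).
#'
#' @seealso [familyMSA()], [readFamilyMSA()], [columnConservation()],
#'   [identityVector()], [msaDistanceMatrix()]
#' @exportClass FamilyMSA
setClass("FamilyMSA",
  representation(
    aln = "AAStringSet",
    species = "character",
    paralog = "character",
    family = "character"
  )
)

setValidity("FamilyMSA", function(object) {
  n <- length(object@aln)
  if (n == 0L)
    return("alignment must contain at least one row")
  w <- Biostrings::width(object@aln)
  if (length(unique(w)) != 1L)
    return("all gapped rows must have identical length")
  if (length(object@species) != n)
    return("species labels must match the number of rows")
  if (length(object@paralog) != n)
    return("paralog tags must match the number of rows")
  ids <- names(object@aln)
  if (is.null(ids) || anyDuplicated(ids))
    return("row ids must be present and unique")
  if (length(object@family) != 1L)
    return("family must be a single string")
  TRUE
})

#' Construct a FamilyMSA
#'
#' @param aln [Biostrings::AAStringSet] (or named character vector) of gapped
#'   rows; names are row ids.
#' @param species character vector of species labels, recycled if length 1.
#' @param paralog character vector of paralog tags (default `NA`).
#' @param family gene-family name.
#' @return A [FamilyMSA-class] object.
#' @examples
#' msa <- familyMSA(c(r1 = "MC-", r2 = "MCA"),
#'                  species = c("human", "mouse"), family = "toy")
#' msaLength(msa)
#' @export
familyMSA <- function(aln, species, paralog = NA_character_, family = "family") {
  if (is.character(aln))
    aln <- Biostrings::AAStringSet(aln)
  n <- length(aln)
  species <- rep_len(as.character(species), n)
  paralog <- rep_len(as.character(paralog), n)
  new("FamilyMSA", aln = aln, species = species, paralog = paralog,
      family = as.character(family))
}

#' @describeIn familyMSA number of rows in the alignment
#' @param x a `FamilyMSA`
#' @export
msaRows <- function(x) length(x@aln)

#' @describeIn familyMSA number of columns in the alignment
#' @export
msaLength <- function(x) unique(Biostrings::width(x@aln))

#' @describeIn familyMSA species label of each row
#' @export
msaSpecies <- function(x) x@species

#' @describeIn familyMSA paralog tag of each row
#' @export
msaParalog <- function(x) x@paralog

#' @describeIn familyMSA the gapped rows as a character vector (named by row
#'   id)
#' @export
gappedRows <- function(x) {
  out <- as.character(x@aln)
  names(out) <- names(x@aln)
  out
}

setMethod("show", "FamilyMSA", function(object) {
  cat("FamilyMSA of family '", object@family, "': ",
      msaRows(object), " rows x ", msaLength(object), " columns, ",
      length(unique(object@species)), " species\n", sep = "")
})

## ---------------------------------------------------------------------------
## CopyNumberPanel: per-species copy counts of the two families.
## ---------------------------------------------------------------------------

#' Per-species copy numbers of two gene families
#'
#' Holds, for each species of a panel, the number of gene copies of family A
#' and family B, plus a flag recording whether the species' genome assembly
#' is complete (incomplete genomes can only lower-bound copy numbers).
#'
#' @slot species unique species labels.
#' @slot copiesA,copiesB non-negative integer copy counts.
#' @slot completeGenome logical flags.
#' @slot maxCopies upper bound used for validation (default 10).
#' @seealso [copyNumberPanel()], [contingencyFromProfiles()],
#'   [chiSquaredIndependence()], [permutationIndependence()]
#' @exportClass CopyNumberPanel
setClass("CopyNumberPanel",
  representation(
    species = "character",
    copiesA = "integer",
    copiesB = "integer",
    completeGenome = "logical",
    maxCopies = "integer"
  )
)

setValidity("CopyNumberPanel", function(object) {
  n <- length(object@species)
  if (n == 0L)
    return("panel must contain at least one species")
  if (anyDuplicated(object@species))
    return("species labels must be unique")
  if (length(object@copiesA) != n || length(object@copiesB) != n ||
      length(object@completeGenome) != n)
    return("all columns must have one entry per species")
  if (any(object@copiesA < 0L) || any(object@copiesB < 0L))
    return("copy counts must be non-negative")
  if (any(object@copiesA > object@maxCopies) ||
      any(object@copiesB > object@maxCopies))
    return(sprintf("copy counts exceed maxCopies = %d", object@maxCopies))
  TRUE
})

#' Construct a copy-number panel
#'
#' @param species character vector of unique species labels.
#' @param copiesA,copiesB non-negative integer copy counts of the two
#'   families.
#' @param completeGenome logical; is the genome assembly complete?
#' @param maxCopies validation upper bound on copy counts.
#' @return A [CopyNumberPanel-class].
#' @examples
#' panel <- copyNumberPanel(c("armadillo", "human", "mouse"),
#'                          copiesA = c(0, 1, 2), copiesB = c(1, 1, 2))
#' panelSpecies(panel)
#' @export
copyNumberPanel <- function(species, copiesA, copiesB,
                            completeGenome = TRUE, maxCopies = 10L) {
  n <- length(species)
  new("CopyNumberPanel",
      species = as.character(species),
      copiesA = as.integer(copiesA),
      copiesB = as.integer(copiesB),
      completeGenome = rep_len(as.logical(completeGenome), n),
      maxCopies = as.integer(maxCopies))
}

#' @describeIn copyNumberPanel species labels
#' @param x a `CopyNumberPanel`
#' @export
panelSpecies <- function(x) x@species

#' @describeIn copyNumberPanel copy counts of family A (named by species)
#' @export
copiesA <- function(x) stats::setNames(x@copiesA, x@species)

#' @describeIn copyNumberPanel copy counts of family B (named by species)
#' @export
copiesB <- function(x) stats::setNames(x@copiesB, x@species)

#' @describeIn copyNumberPanel the panel as a data.frame
#' @export
panelAsDataFrame <- function(x) {
  data.frame(species = x@species, copies_a = x@copiesA, copies_b = x@copiesB,
             complete_genome = x@completeGenome,
             stringsAsFactors = FALSE)
}

setMethod("show", "CopyNumberPanel", function(object) {
  cat("CopyNumberPanel: ", length(object@species), " species; copy levels A = {",
      paste(sort(unique(object@copiesA)), collapse = ","), "}, B = {",
      paste(sort(unique(object@copiesB)), collapse = ","), "}\n", sep = "")
})

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' Result of a copy-number independence test
#'
#' @slot statistic Pearson chi-squared statistic.
#' @slot df degrees of freedom (`NA` for the permutation method).
#' @slot pValue the p-value.
#' @slot method `"asymptotic"` or `"permutation"`.
#' @slot nPerm number of permutations (`NA` for asymptotic).
#' @slot table the observed contingency table.
#' @slot seed RNG seed used (`NA` for asymptotic).
#' @exportClass IndependenceTest
setClass("IndependenceTest",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 method = "character", nPerm = "numeric", table = "matrix",
                 seed = "numeric"))

setValidity("IndependenceTest", function(object) {
  if (object@statistic < 0) return("statistic must be non-negative")
  if (object@pValue < 0 || object@pValue > 1) return("p-value out of [0, 1]")
  if (!object@method %in% c("asymptotic", "permutation"))
    return("method must be 'asymptotic' or 'permutation'")
  TRUE
})

setMethod("show", "IndependenceTest", function(object) {
  cat(sprintf("Copy-number independence test (%s)\n", object@method))
  cat(sprintf("  X-squared = %.4g", object@statistic))
  if (!is.na(object@df)) cat(sprintf(", df = %d", as.integer(object@df)))
  if (!is.na(object@nPerm)) cat(sprintf(", permutations = %d", as.integer(object@nPerm)))
  cat(sprintf(", p-value = %.4g\n", object@pValue))
})

#' Result of a Pearson correlation between two evolutionary signals
#'
#' Used by the identity-vector, mirror-tree and expression correlations.
#'
#' @slot r Pearson correlation coefficient.
#' @slot nPairs number of paired observations entering the correlation.
#' @slot pValue permutation p-value (`NA` when no null was run).
#' @slot commonLabels labels shared by the two inputs.
#' @slot method free-text description of the correlation mode.
#' @slot nPerm number of permutations (`NA` when no null was run).
#' @slot seed RNG seed used (`NA` when no null was run).
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(r = "numeric", nPairs = "numeric", pValue = "numeric",
                 commonLabels = "character", method = "character",
                 nPerm = "numeric", seed = "numeric"))

setValidity("CorrelationResult", function(object) {
  if (!is.na(object@r) && (object@r < -1 - 1e-12 || object@r > 1 + 1e-12))
    return("r out of [-1, 1]")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("p-value out of [0, 1]")
  TRUE
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("%s: r = %.4g over n = %d pairs", object@method, object@r,
              as.integer(object@nPairs)))
  if (!is.na(object@pValue))
    cat(sprintf(", permutation p = %.4g (%d permutations)",
                object@pValue, as.integer(object@nPerm)))
  cat("\n")
})

#' Result of best-score read-to-paralog assignment
#'
#' Partition of the input reads into uniquely assigned reads, ex-aequo
#' (tied-best-score) discards and unmapped discards.
#'
#' @slot assigned named character vector: read id -> transcript id.
#' @slot discardedExAequo read ids whose best score was tied.
#' @slot discardedUnmapped read ids with no candidate above the threshold.
#' @slot minScore the score threshold used.
#' @exportClass ReadAssignment
setClass("ReadAssignment",
  representation(assigned = "character", discardedExAequo = "character",
                 discardedUnmapped = "character", minScore = "numeric"))

setMethod("show", "ReadAssignment", function(object) {
  cat(sprintf(
    "ReadAssignment: %d assigned, %d ex-aequo discarded, %d unmapped (min score %.6g)\n",
    length(object@assigned), length(object@discardedExAequo),
    length(object@discardedUnmapped), object@minScore))
})

#' @describeIn assignBestScore assigned reads as a named character vector
#'   (read id -> transcript id)
#' @param x a `ReadAssignment`
#' @export
assignedReads <- function(x) x@assigned

#' @describeIn assignBestScore read ids discarded because of tied best scores
#' @export
discardedExAequo <- function(x) x@discardedExAequo

#' @describeIn assignBestScore read ids with no candidate above the threshold
#' @export
discardedUnmapped <- function(x) x@discardedUnmapped

#' RPKM expression profile of genes across samples
#'
#' @slot rpkm genes x samples matrix of RPKM values.
#' @slot counts genes x samples matrix of assigned read counts.
#' @slot geneLength representative transcript length (nt) per gene.
#' @slot totalMapped total mapped reads per sample.
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
  representation(rpkm = "matrix", counts = "matrix",
                 geneLength = "numeric", totalMapped = "numeric"))

setValidity("ExpressionProfile", function(object) {
  if (any(object@rpkm < 0)) return("RPKM values must be non-negative")
  if (!identical(dim(object@rpkm), dim(object@counts)))
    return("rpkm and counts must have identical dimensions")
  if (length(object@geneLength) != nrow(object@rpkm))
    return("one transcript length per gene required")
  if (length(object@totalMapped) != ncol(object@rpkm))
    return("one total-mapped count per sample required")
  TRUE
})

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile: %d genes x %d samples (RPKM)\n",
              nrow(object@rpkm), ncol(object@rpkm)))
})

#' @describeIn expressionProfile the RPKM matrix
#' @param x an `ExpressionProfile`
#' @export
rpkmMatrix <- function(x) x@rpkm

#' @describeIn expressionProfile the raw count matrix
#' @export
countMatrix <- function(x) x@counts
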