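## Pairwise protein alignment with EMBOSS-style reporting.
##
## The dynamic programming itself is delegated to
## Biostrings::pairwiseAlignment (affine gaps: a gap of length L costs
## gapOpening + L * gapExtension, the needle/water convention).  What this
## module adds is the reporting layer those tools print: full-length global
## alignments with penalty-free end gaps, and percent identity / similarity
## over the alignment length including gap columns.

#' Pairwise alignment with identity and similarity percentages
#'
#' @slot alignedA,alignedB gapped aligned strings (equal length).
#' @slot score optimal alignment score.
#' @slot identityPct percent of alignment columns with identical residues.
#' @slot similarityPct percent of columns whose residue pair has a strictly
#'   positive substitution score (identities included).
#' @slot type `"global"` or `"local"`.
#' @exportClass PairAlignment
setClass("PairAlignment",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", identityPct = "numeric",
                 similarityPct = "numeric", type = "character"))

setValidity("PairAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  if (object@identityPct > object@similarityPct + 1e-9)
    return("identity cannot exceed similarity")
  if (object@similarityPct > 100 + 1e-9)
    return("similarity cannot exceed 100")
  TRUE
})

setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment (%s): length %d, score %.4g\n", object@type,
              nchar(object@alignedA), object@score))
  cat(sprintf("  identity %.1f%%, similarity %.1f%%\n",
              object@identityPct, object@similarityPct))
})

#' @describeIn alignPair alignment score
#' @param x a `PairAlignment`
#' @export
alignmentScore <- function(x) x@score

#' @describeIn alignPair percent identity over the alignment length
#' @export
identityPct <- function(x) x@identityPct

#' @describeIn alignPair percent similarity over the alignment length
#' @export
similarityPct <- function(x) x@similarityPct

#' @describeIn alignPair the two gapped aligned strings
#' @export
alignedStrings <- function(x) c(a = x@alignedA, b = x@alignedB)

.resolveMatrix <- function(substitutionMatrix) {
  if (is.matrix(substitutionMatrix)) return(substitutionMatrix)
  e <- new.env()
  utils::data(list = substitutionMatrix, package = "Biostrings", envir = e)
  get(substitutionMatrix, envir = e)
}

.checkAlphabet <- function(res, mat, label) {
  letters <- unique(strsplit(res, "")[[1]])
  bad <- setdiff(letters, rownames(mat))
  if (length(bad))
    stop(sprintf("sequence %s contains residues outside the substitution matrix alphabet: %s",
                 label, paste(bad, collapse = ", ")), call. = FALSE)
}

## identity / similarity over gapped aligned strings, denominator = full
## alignment length (gap columns included), similarity = identities plus
## strictly positive substitution scores.
.alignmentStats <- function(alnA, alnB, mat) {
  a <- strsplit(alnA, "")[[1]]
  b <- strsplit(alnB, "")[[1]]
  len <- length(a)
  if (len == 0L)
    return(list(identity = 0, similarity = 0))
  both <- a != "-" & b != "-"
  ident <- sum(both & a == b)
  pos <- sum(mat[cbind(a[both], b[both])] > 0)
  list(identity = 100 * ident / len, similarity = 100 * pos / len)
}

#' Pairwise sequence alignment with EMBOSS-style reporting
#'
#' Computes an optimal affine-gap pairwise alignment and reports percent
#' identity and percent similarity the way the classic needle/water tools
#' do: the denominator is the full alignment length including gap columns,
#' and "similar" means a strictly positive substitution-matrix score.
#'
#' In global mode end gaps are penalty-free by default (the needle default),
#' and the reported alignment is padded to cover both sequences end to end.
#' In local mode the highest-scoring segment pair is reported; when no
#' residue pair scores positively the alignment is empty with score 0.
#'
#' @param a,b sequences (character or `XString`); same molecule type.
#' @param type `"global"` (Needleman-Wunsch) or `"local"`
#'   (Smith-Waterman).
#' @param substitutionMatrix a scoring matrix or the name of one shipped
#'   with Biostrings (default `"BLOSUM62"`).
#' @param gapOpening,gapExtension affine gap penalties (positive costs);
#'   defaults 10 and 0.5, the needle/water defaults.  Requires
#'   `gapOpening >= gapExtension >= 0`.
#' @param endGapsFree logical; in global mode, are end gaps penalty-free?
#' @return A [PairAlignment-class].
#' @examples
#' pa <- alignPair("HEAGAWGHEE", "PAWHEAE")
#' identityPct(pa)
#' @export
alignPair <- function(a, b, type = c("global", "local"),
                      substitutionMatrix = "BLOSUM62",
                      gapOpening = 10, gapExtension = 0.5,
                      endGapsFree = TRUE) {
  type <- match.arg(type)
  if (!(gapOpening >= gapExtension && gapExtension >= 0))
    stop("require gapOpening >= gapExtension >= 0", call. = FALSE)
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  mat <- .resolveMatrix(substitutionMatrix)
  .checkAlphabet(a, mat, "a")
  .checkAlphabet(b, mat, "b")

  bioType <- if (type == "local") "local"
             else if (endGapsFree) "overlap" else "global"
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat,
    gapOpening = gapOpening, gapExtension = gapExtension,
    type = bioType)

  if (type == "local" && Biostrings::score(pa) <= 0) {
    ## Smith-Waterman floors at zero: no positive-scoring segment exists.
    return(new("PairAlignment", alignedA = "", alignedB = "", score = 0,
               identityPct = 0, similarityPct = 0, type = "local"))
  }

  midA <- as.character(Biostrings::alignedPattern(pa))
  midB <- as.character(Biostrings::alignedSubject(pa))

  if (type == "global") {
    ## Pad to a full-length alignment: unaligned prefixes/suffixes of each
    ## sequence become end-gap columns (the way needle prints them).
    sA <- Biostrings::start(Biostrings::pattern(pa))
    eA <- Biostrings::end(Biostrings::pattern(pa))
    sB <- Biostrings::start(Biostrings::subject(pa))
    eB <- Biostrings::end(Biostrings::subject(pa))
    preA <- substr(a, 1L, sA - 1L); sufA <- substr(a, eA + 1L, nchar(a))
    preB <- substr(b, 1L, sB - 1L); sufB <- substr(b, eB + 1L, nchar(b))
    alnA <- paste0(preA, strrep("-", nchar(preB)), midA,
                   sufA, strrep("-", nchar(sufB)))
    alnB <- paste0(strrep("-", nchar(preA)), preB, midB,
                   strrep("-", nchar(sufA)), sufB)
  } else {
    alnA <- midA; alnB <- midB
  }

  st <- .alignmentStats(alnA, alnB, mat)
  new("PairAlignment", alignedA = alnA, alignedB = alnB,
      score = Biostrings::score(pa),
      identityPct = st$identity, similarityPct = st$similarity,
      type = type)
}

#' @rdname alignPair
#' @export
globalAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5,
                        endGapsFree = TRUE) {
  alignPair(a, b, type = "global", substitutionMatrix = substitutionMatrix,
            gapOpening = gapOpening, gapExtension = gapExtension,
            endGapsFree = endGapsFree)
}

#' @rdname alignPair
#' @export
localAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                       gapOpening = 10, gapExtension = 0.5) {
  alignPair(a, b, type = "local", substitutionMatrix = substitutionMatrix,
            gapOpening = gapOpening, gapExtension = gapExtension)
}
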