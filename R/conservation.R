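## Alignment-column conservation, positional motif scanning and repeat
## masking.  Offsets are 1-based throughout, matching the field's "Cys-34"
## style of naming residues.

#' Per-column conservation of a family alignment
#'
#' A column is invariant when every row carries the same residue and no row
#' carries a gap.  The per-residue tally of invariant columns (e.g. "how
#' many invariant cysteines") is the headline statistic for conserved-region
#' analysis.
#'
#' @param msa a [FamilyMSA-class].
#' @return A data.frame with one row per alignment column: `column`
#'   (1-based), `residue` (the invariant residue, else `NA`),
#'   `is_invariant`, `gap_count`.
#' @seealso [invariantResidueCounts()]
#' @examples
#' msa <- familyMSA(c(r1 = "MC-", r2 = "MCA"), species = c("s1", "s2"))
#' columnConservation(msa)
#' @export
columnConservation <- function(msa) {
  stopifnot(is(msa, "FamilyMSA"))
  m <- do.call(rbind, strsplit(gappedRows(msa), ""))
  ncol_ <- ncol(m)
  gapCount <- colSums(m == "-")
  residue <- m[1L, ]
  allSame <- vapply(seq_len(ncol_), function(j) all(m[, j] == m[1L, j]),
                    logical(1))
  isInv <- allSame & gapCount == 0L
  data.frame(column = seq_len(ncol_),
             residue = ifelse(isInv, residue, NA_character_),
             is_invariant = isInv,
             gap_count = as.integer(gapCount),
             stringsAsFactors = FALSE)
}

#' Tally invariant columns by residue
#'
#' @param conservation output of [columnConservation()].
#' @return Named integer vector: residue -> number of invariant columns.
#' @export
invariantResidueCounts <- function(conservation) {
  res <- conservation$residue[conservation$is_invariant]
  if (!length(res)) return(stats::setNames(integer(0), character(0)))
  tab <- table(res)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a conservation report as TSV
#'
#' @param conservation output of [columnConservation()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeConservationTsv <- function(conservation, path) {
  utils::write.table(conservation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Motif patterns
## ---------------------------------------------------------------------------

#' Parse a positional motif pattern
#'
#' Patterns are ordered residue sets in a PROSITE-like syntax: a plain
#' letter is a fixed residue, `[AT]` is an alternative set, and `X` is a
#' wildcard matching any residue (including `X` itself).  Elements may be
#' separated by `-` for readability: `"C-X-X-C"` and `"CXXC"` parse
#' identically, as does the fuzzy-cysteine pattern `"C-F-[AT]-C-[FY]"`.
#'
#' @param pattern the pattern string.
#' @param anchor optional 1-based offset where the motif is expected to
#'   start (e.g. 34 for a motif anchored at Cys-34).
#' @return An object of class `MotifPattern`: a list of character vectors
#'   (one per element; `NULL`-free), with the anchor as an attribute.
#' @examples
#' motifPattern("C-F-[AT]-C-[FY]", anchor = 34)
#' @export
motifPattern <- function(pattern, anchor = NULL) {
  pattern <- gsub("-", "", pattern, fixed = TRUE)
  tokens <- regmatches(pattern,
                       gregexpr("\\[[A-Z]+\\]|[A-Z]", pattern))[[1]]
  if (!length(tokens) || nchar(pattern) != sum(nchar(tokens)))
    stop(sprintf("cannot parse motif pattern '%s'", pattern), call. = FALSE)
  elements <- lapply(tokens, function(tok) {
    if (startsWith(tok, "["))
      strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1]]
    else if (tok == "X") "X"   # wildcard sentinel
    else tok
  })
  wildcard <- vapply(tokens, identical, logical(1), "X")
  if (!is.null(anchor)) {
    anchor <- as.integer(anchor)
    stopifnot(length(anchor) == 1L, anchor >= 1L)
  }
  structure(list(elements = elements, wildcard = unname(wildcard)),
            anchor = anchor, class = "MotifPattern")
}

#' @export
print.MotifPattern <- function(x, ...) {
  txt <- mapply(function(el, wc) {
    if (wc) "X" else if (length(el) > 1L) paste0("[", paste(el, collapse = ""), "]")
    else el
  }, x$elements, x$wildcard)
  cat("MotifPattern:", paste(txt, collapse = "-"))
  if (!is.null(attr(x, "anchor")))
    cat("  (anchored at offset", attr(x, "anchor"), ")")
  cat("\n")
  invisible(x)
}

#' Scan a sequence for a positional motif
#'
#' Reports every 1-based offset at which the motif matches; overlapping
#' matches are all reported.  Scanning operates on ungapped residues: pass
#' sequences, not alignment rows (gaps are rejected).
#'
#' @param seq a sequence (character or `XString`), ungapped.
#' @param pattern a `MotifPattern` from [motifPattern()], or a pattern
#'   string.
#' @return Integer vector of match offsets.  If the pattern carries an
#'   anchor, the attribute `anchor_matched` reports whether the anchor
#'   offset is among the matches.
#' @examples
#' scanMotif("ACFACY", "C-X-X-C")
#' @export
scanMotif <- function(seq, pattern) {
  if (is.character(pattern) || !inherits(pattern, "MotifPattern"))
    pattern <- motifPattern(pattern)
  s <- strsplit(as.character(seq), "")[[1]]
  if (any(s == "-"))
    stop("scanMotif() operates on ungapped sequences; degap() first",
         call. = FALSE)
  k <- length(pattern$elements)
  n <- length(s)
  hits <- integer(0)
  if (k <= n && k > 0L) {
    ok <- rep(TRUE, n - k + 1L)
    for (j in seq_len(k)) {
      if (pattern$wildcard[j]) next
      ok <- ok & s[seq.int(j, j + n - k)] %in% pattern$elements[[j]]
    }
    hits <- which(ok)
  }
  anchor <- attr(pattern, "anchor")
  if (!is.null(anchor))
    attr(hits, "anchor_matched") <- anchor %in% hits
  hits
}

## ---------------------------------------------------------------------------
## Interval masking
## ---------------------------------------------------------------------------

#' Read a 1-based inclusive interval table
#'
#' Three tab-separated columns: sequence name, start, end.  Coordinates are
#' 1-based and inclusive on both ends -- note this differs from BED proper,
#' which is 0-based half-open.
#'
#' @param path path to the TSV file (no header, or a header line starting
#'   with `name`).
#' @return data.frame with columns `name`, `start`, `end`.
#' @export
readIntervalTsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("^name\\b", first)
  df <- utils::read.table(path, sep = "\t", header = header,
                          col.names = c("name", "start", "end"),
                          stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end))
    stop("interval with start > end", call. = FALSE)
  df
}

#' Mask intervals of a sequence
#'
#' Residues inside the intervals are replaced by the ambiguity letter of the
#' molecule type: `N` for nucleotide, `X` for protein.  Length is unchanged
#' and masking is idempotent.
#'
#' @param seq a sequence (character or `XString`).
#' @param intervals data.frame with `start`, `end` columns (1-based,
#'   inclusive), e.g. from [readIntervalTsv()]; an empty data.frame leaves
#'   the sequence unchanged.
#' @param molecule `"nucleotide"` or `"protein"`.
#' @return The masked sequence as a character string.
#' @examples
#' maskIntervals("ACGTACGT", data.frame(start = 3, end = 4))
#' @export
maskIntervals <- function(seq, intervals,
                          molecule = c("nucleotide", "protein")) {
  molecule <- match.arg(molecule)
  s <- as.character(seq)
  n <- nchar(s)
  if (is.null(intervals) || nrow(intervals) == 0L) return(s)
  if (any(intervals$start < 1L) || any(intervals$end > n) ||
      any(intervals$start > intervals$end))
    stop(sprintf("interval out of bounds for sequence of length %d", n),
         call. = FALSE)
  maskChar <- if (molecule == "nucleotide") "N" else "X"
  chars <- strsplit(s, "")[[1]]
  for (i in seq_len(nrow(intervals)))
    chars[intervals$start[i]:intervals$end[i]] <- maskChar
  paste(chars, collapse = "")
}
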