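## FASTA input/output.  Headers use a pipe-delimited dialect
## "id|species|paralog"; missing fields default sensibly (species <- id,
## paralog <- NA).  Extra pipe-delimited fields are tolerated and logged.

.parseFastaHeaders <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, `[`, character(1), 1L)
  species <- vapply(parts, function(p)
    if (length(p) >= 2L && nzchar(p[2L])) p[2L] else p[1L], character(1))
  paralog <- vapply(parts, function(p)
    if (length(p) >= 3L && nzchar(p[3L])) p[3L] else NA_character_,
    character(1))
  extra <- vapply(parts, function(p) length(p) > 3L, logical(1))
  if (any(extra))
    cfLog(sprintf("%d FASTA header(s) carry extra '|' fields; ignored",
                  sum(extra)), "warn")
  list(id = id, species = species, paralog = paralog)
}

## Scan the raw file to report the line number of a header with no sequence
## (the one malformation Biostrings reports unhelpfully).
.checkFastaWellFormed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    body <- if (from > to) character(0) else lines[from:to]
    if (sum(nchar(gsub("\\s", "", body))) == 0L)
      stop(sprintf("malformed FASTA record at line %d of '%s': header without sequence",
                   hdr[i], path), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read sequences from a FASTA file
#'
#' Reads ungapped protein or nucleotide sequences.  Headers are parsed with
#' the pipe dialect `id|species|paralog`; when the species field is absent
#' the id doubles as the species label.  Species and paralog annotations are
#' attached as [S4Vectors::mcols()] metadata columns.
#'
#' @param path path to a FASTA file.
#' @param molecule `"protein"` or `"nucleotide"`.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet] with
#'   metadata columns `species` and `paralog`.  An empty file yields an
#'   empty set.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1|Homo_sapiens", "MCP"), tf)
#' seqs <- readFastaSeqs(tf)
#' S4Vectors::mcols(seqs)$species
#' @export
readFastaSeqs <- function(path, molecule = c("protein", "nucleotide")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (file.size(path) == 0L || !any(grepl("^>", readLines(path, warn = FALSE)))) {
    empty <- if (molecule == "protein") Biostrings::AAStringSet()
             else Biostrings::DNAStringSet()
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
      species = character(0), paralog = character(0))
    return(empty)
  }
  .checkFastaWellFormed(path)
  seqs <- if (molecule == "protein") Biostrings::readAAStringSet(path)
          else Biostrings::readDNAStringSet(path)
  meta <- .parseFastaHeaders(names(seqs))
  if (anyDuplicated(meta$id))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
         call. = FALSE)
  if (any(grepl("-", as.character(seqs), fixed = TRUE)))
    stop("gap characters found; use readFamilyMSA() for gapped alignments",
         call. = FALSE)
  names(seqs) <- meta$id
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    species = meta$species, paralog = meta$paralog)
  seqs
}

#' Write sequences to a FASTA file
#'
#' Inverse of [readFastaSeqs()]: emits `id|species|paralog` headers (paralog
#' omitted when `NA`), so that a write/read round trip reproduces ids,
#' residues and metadata.
#'
#' @param seqs an `XStringSet` with optional `species`/`paralog` metadata
#'   columns, or a named character vector.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named", call. = FALSE)
  meta <- S4Vectors::mcols(seqs)
  species <- if (!is.null(meta$species)) meta$species else ids
  paralog <- if (!is.null(meta$paralog)) meta$paralog else rep(NA_character_, length(seqs))
  headers <- ifelse(is.na(paralog),
                    paste(ids, species, sep = "|"),
                    paste(ids, species, paralog, sep = "|"))
  out <- seqs
  names(out) <- headers
  Biostrings::writeXStringSet(out, filepath = path)
  invisible(path)
}

#' Read a gapped family alignment from FASTA
#'
#' Rows may contain `-` gaps and must all have the same length.  Metadata
#' follow the same `id|species|paralog` header dialect as [readFastaSeqs()].
#'
#' @param path path to a gapped FASTA file.
#' @param family gene-family name attached to the object.
#' @return A [FamilyMSA-class].
#' @export
readFamilyMSA <- function(path, family = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  .checkFastaWellFormed(path)
  seqs <- Biostrings::readAAStringSet(path)
  meta <- .parseFastaHeaders(names(seqs))
  names(seqs) <- meta$id
  familyMSA(seqs, species = meta$species, paralog = meta$paralog,
            family = family)
}

#' Write a family alignment to gapped FASTA
#'
#' @param msa a [FamilyMSA-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeFamilyMSA <- function(msa, path) {
  stopifnot(is(msa, "FamilyMSA"))
  seqs <- msa@aln
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    species = msa@species, paralog = msa@paralog)
  writeFastaSeqs(seqs, path)
}

#' Remove gaps from an alignment row
#'
#' @param x character vector of gapped sequences.
#' @return character vector with all `-` removed.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)
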