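## Paralog-aware expression quantification: best-score read assignment with
## ex-aequo discarding, RPKM, and cross-species expression correlation.
##
## The upstream read scorer is pluggable: any table of (read_id,
## transcript_id, score) rows works.  A bundled ungapped local scorer is
## provided so the whole path is testable without external aligners.

#' Read a read-vs-transcript score table from TSV
#'
#' Tab-separated columns `read_id`, `transcript_id`, `score` (header
#' required).
#'
#' @param path path to the TSV file.
#' @return data.frame with those three columns.
#' @export
readScoreTable <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("read_id", "transcript_id", "score")
  if (!all(need %in% names(df)))
    stop("score TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$score <- as.numeric(df$score)
  if (any(!is.finite(df$score)))
    stop("non-finite scores in score table", call. = FALSE)
  if (anyDuplicated(df[c("read_id", "transcript_id")]))
    stop("duplicate (read_id, transcript_id) pairs", call. = FALSE)
  df[need]
}

#' Read transcript metadata from TSV
#'
#' Tab-separated columns `transcript_id`, `gene`, `paralog`, `length_nt`
#' (header required).
#'
#' @param path path to the TSV file.
#' @return data.frame with those columns.
#' @export
readTranscriptMeta <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene", "paralog", "length_nt")
  if (!all(need %in% names(df)))
    stop("transcript metadata TSV needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df$length_nt <- as.integer(df$length_nt)
  if (any(df$length_nt <= 0L))
    stop("transcript lengths must be positive", call. = FALSE)
  df[need]
}

#' Best-score read assignment with ex-aequo discarding
#'
#' For every read, candidate transcripts scoring at least `minScore` are
#' ranked.  A unique maximum assigns the read to that transcript; a tied
#' maximum (an ex-aequo read) is discarded, because a read that matches two
#' paralogs equally well cannot be attributed reliably; a read with no
#' candidate above the threshold is discarded as unmapped.  Ties are
#' detected after rounding scores to 6 decimals (floating-point hygiene).
#' The result is deterministic and independent of input row order.
#'
#' @param table score table (data.frame `read_id`, `transcript_id`,
#'   `score`), e.g. from [readScoreTable()] or [scoreReads()].
#' @param meta transcript metadata (data.frame with `transcript_id`);
#'   every transcript in `table` must be present.
#' @param minScore score threshold for a candidate to count as mapped.
#' @return A [ReadAssignment-class].
#' @examples
#' tab <- data.frame(read_id = c("r1", "r1", "r2", "r2"),
#'                   transcript_id = c("tA", "tB", "tA", "tB"),
#'                   score = c(100, 90, 95, 95))
#' meta <- data.frame(transcript_id = c("tA", "tB"), gene = "g",
#'                    paralog = c("a", "b"), length_nt = 1000L)
#' assignBestScore(tab, meta, minScore = 50)
#' @export
assignBestScore <- function(table, meta, minScore) {
  stopifnot(is.finite(minScore))
  missing_tx <- setdiff(unique(table$transcript_id), meta$transcript_id)
  if (length(missing_tx))
    stop("transcripts without metadata: ",
         paste(missing_tx, collapse = ", "), call. = FALSE)
  ## canonical order makes the result independent of input row order
  table <- table[order(table$read_id, table$transcript_id), , drop = FALSE]
  score <- round(table$score, 6L)
  reads <- unique(table$read_id)

  assigned <- character(0); exaequo <- character(0); unmapped <- character(0)
  byRead <- split(seq_len(nrow(table)), table$read_id)
  for (rid in names(byRead)) {
    idx <- byRead[[rid]]
    ok <- idx[score[idx] >= minScore]
    if (!length(ok)) { unmapped <- c(unmapped, rid); next }
    s <- score[ok]
    best <- ok[s == max(s)]
    if (length(best) > 1L) exaequo <- c(exaequo, rid)
    else assigned[rid] <- table$transcript_id[best]
  }
  new("ReadAssignment", assigned = assigned,
      discardedExAequo = exaequo, discardedUnmapped = unmapped,
      minScore = as.numeric(minScore))
}

#' Count assigned reads per transcript and per gene
#'
#' @param assignment a [ReadAssignment-class].
#' @param meta transcript metadata (columns `transcript_id`, `gene`);
#'   transcripts with zero assigned reads appear with count 0.
#' @return List with named integer vectors `perTranscript` and `perGene`;
#'   gene counts are the sums over their transcripts, and both sum to the
#'   number of assigned reads.
#' @export
countAssigned <- function(assignment, meta) {
  stopifnot(is(assignment, "ReadAssignment"))
  tx <- factor(assignment@assigned, levels = meta$transcript_id)
  perTranscript <- stats::setNames(as.integer(table(tx)),
                                   meta$transcript_id)
  perGene <- vapply(split(perTranscript, meta$gene), sum, integer(1))
  list(perTranscript = perTranscript, perGene = perGene)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count * 1e9 / (length_nt * totalMapped)`.
#'
#' @param count assigned read count(s).
#' @param lengthNt transcript length(s) in nucleotides (> 0).
#' @param totalMapped total mapped reads in the sample (> 0).
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)   # 10
#' @export
rpkm <- function(count, lengthNt, totalMapped) {
  if (any(lengthNt <= 0)) stop("transcript length must be > 0", call. = FALSE)
  if (any(totalMapped <= 0)) stop("total mapped reads must be > 0",
                                  call. = FALSE)
  count * 1e9 / (lengthNt * totalMapped)
}

#' Build an RPKM expression profile across samples
#'
#' Assembles per-gene counts per sample into an [ExpressionProfile-class].
#' By default `totalMapped` is the number of reads assigned to any
#' transcript of the sample's index (the in-index total); pass explicit
#' library sizes to normalise by sequencing depth instead.
#'
#' @param counts genes x samples integer matrix of assigned read counts.
#' @param geneLength named vector of representative transcript lengths
#'   (nt), one per gene.
#' @param totalMapped named vector of totals per sample; default
#'   `colSums(counts)`.
#' @return An [ExpressionProfile-class].
#' @export
expressionProfile <- function(counts, geneLength,
                              totalMapped = colSums(counts)) {
  counts <- as.matrix(counts)
  geneLength <- geneLength[rownames(counts)]
  if (any(is.na(geneLength)))
    stop("geneLength must cover every gene in counts", call. = FALSE)
  rp <- sweep(counts * 1e9, 1L, geneLength, "/")
  rp <- sweep(rp, 2L, totalMapped, "/")
  new("ExpressionProfile", rpkm = rp, counts = counts,
      geneLength = as.numeric(geneLength),
      totalMapped = as.numeric(totalMapped))
}

#' Cross-sample expression correlation of two genes
#'
#' Pearson correlation between the two genes' RPKM vectors across samples;
#' a strong negative value indicates anti-regulated expression.
#'
#' @param profile an [ExpressionProfile-class].
#' @param geneA,geneB gene names (rows of the profile).
#' @param samples optional subset of sample names; default all.
#' @return A [CorrelationResult-class].  A constant expression vector
#'   raises an error rather than silently returning 0.
#' @export
expressionCorrelation <- function(profile, geneA, geneB, samples = NULL) {
  stopifnot(is(profile, "ExpressionProfile"))
  rp <- profile@rpkm
  if (!all(c(geneA, geneB) %in% rownames(rp)))
    stop("gene not in profile: ",
         paste(setdiff(c(geneA, geneB), rownames(rp)), collapse = ", "),
         call. = FALSE)
  if (is.null(samples)) {
    samples <- colnames(rp)
    if (is.null(samples)) samples <- seq_len(ncol(rp))
  }
  if (length(samples) < 3L)
    stop("need >= 3 samples with both genes quantified", call. = FALSE)
  va <- rp[geneA, samples]; vb <- rp[geneB, samples]
  r <- .pearson(va, vb, "expression correlation")
  new("CorrelationResult", r = r, nPairs = as.numeric(length(samples)),
      pValue = NA_real_, commonLabels = as.character(samples),
      method = "expression correlation", nPerm = NA_real_,
      seed = NA_real_)
}

#' Score reads against transcripts (bundled ungapped local scorer)
#'
#' A self-contained stand-in for an external read aligner: each read is
#' scored against each transcript by its best ungapped local segment with
#' match +1 / mismatch -2 (gaps are forbidden via prohibitive penalties, so
#' the dynamic program reduces to the best-scoring ungapped diagonal run).
#'
#' @param reads named `DNAStringSet` (or character vector) of reads.
#' @param transcripts named `DNAStringSet` (or character vector) of
#'   transcripts.
#' @param match,mismatch scoring parameters (defaults +1 / -2).
#' @return data.frame `read_id`, `transcript_id`, `score` ready for
#'   [assignBestScore()].
#' @export
scoreReads <- function(reads, transcripts, match = 1, mismatch = -2) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (is.character(transcripts))
    transcripts <- Biostrings::DNAStringSet(transcripts)
  if (is.null(names(reads)) || is.null(names(transcripts)))
    stop("reads and transcripts must be named", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  out <- vector("list", length(transcripts))
  for (j in seq_along(transcripts)) {
    pa <- Biostrings::pairwiseAlignment(
      reads, transcripts[[j]], substitutionMatrix = mat,
      gapOpening = 1e6, gapExtension = 1e6, type = "local",
      scoreOnly = TRUE)
    out[[j]] <- data.frame(read_id = names(reads),
                           transcript_id = names(transcripts)[j],
                           score = pmax(pa, 0),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
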