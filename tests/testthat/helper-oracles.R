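## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: the aligner oracle enumerates every gapped
## alignment by recursion, the chi-squared oracle evaluates the definition
## with explicit loops, and the Pearson oracle is the raw sum formula.

## BLOSUM62 restricted to a toy 3-letter alphabet for enumeration tests.
toyMatrix <- function(letters = c("A", "C", "G")) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[letters, letters]
}

## Best global alignment score by exhaustive enumeration of all column
## sequences (match / gap-in-b / gap-in-a), with incremental affine-gap
## accounting.  endFree makes gap runs touching either end cost nothing.
oracleGlobalScore <- function(a, b, mat, go, ge, endFree = TRUE) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  ## gapA/gapB: length of the open '-' run in that row (0 = none; never both
  ## open at once); startA/startB: does the open run extend back to col 1?
  ## col: index of the column about to be emitted (1-based).
  rec <- function(i, j, col, s, gapA, gapB, startA, startB) {
    if (i > na && j > nb) {
      if (!endFree) {           # trailing open runs: free iff endFree
        if (gapA > 0L) s <- s - (go + ge * gapA)
        if (gapB > 0L) s <- s - (go + ge * gapB)
      }
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    ## cost of closing an open run now (runs reaching col 1 are end gaps)
    sA <- if (gapA > 0L && !(endFree && startA)) go + ge * gapA else 0
    sB <- if (gapB > 0L && !(endFree && startB)) go + ge * gapB else 0
    if (i <= na && j <= nb)     # residue-residue column closes both runs
      rec(i + 1L, j + 1L, col + 1L, s - sA - sB + mat[A[i], B[j]],
          0L, 0L, FALSE, FALSE)
    if (i <= na)                # A[i] over '-' in row B: extend/open gapB
      rec(i + 1L, j, col + 1L, s - sA,
          0L, gapB + 1L, FALSE, if (gapB > 0L) startB else col == 1L)
    if (j <= nb)                # '-' in row A under B[j]: extend/open gapA
      rec(i, j + 1L, col + 1L, s - sB,
          gapA + 1L, 0L, if (gapA > 0L) startA else col == 1L, FALSE)
  }
  rec(1L, 1L, 1L, 0, 0L, 0L, FALSE, FALSE)
  best
}

## Best local alignment score: max over all substring pairs of the best
## end-penalised global alignment, floored at zero.
oracleLocalScore <- function(a, b, mat, go, ge) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(A)) for (i2 in i1:length(A)) {
    subA <- paste(A[i1:i2], collapse = "")
    for (j1 in seq_along(B)) for (j2 in j1:length(B)) {
      subB <- paste(B[j1:j2], collapse = "")
      s <- oracleGlobalScore(subA, subB, mat, go, ge, endFree = FALSE)
      if (s > best) best <- s
    }
  }
  best
}

## Pearson chi-squared statistic straight from the definition.
oracleChi2 <- function(tab) {
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    E <- rs[i] * cs[j] / n
    s <- s + (tab[i, j] - E)^2 / E
  }
  unname(s)
}

## Pearson correlation from the raw sum formula.
oraclePearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

## Exhaustive window check for motif scanning.
oracleMotifScan <- function(seq, elements, wildcard) {
  s <- strsplit(seq, "")[[1]]
  k <- length(elements); n <- length(s)
  if (k > n) return(integer(0))
  hits <- integer(0)
  for (off in seq_len(n - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (wildcard[j]) next
      if (!(s[off + j - 1L] %in% elements[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

## Random protein sequence over a given alphabet.
randSeq <- function(n, alphabet = c("A", "C", "G")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
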