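## Identity-percent vectors and mirror-tree correlation.
##
## Pairwise identity between two rows of the same alignment is computed
## directly on the aligned strings: columns where both rows are gaps are
## excluded from the denominator, columns where exactly one row is a gap
## count as mismatches, and identical non-gap residues count as matches.
## This is deterministic and needs no realignment.

.pairIdentityFromRows <- function(a, b) {
  both_gap <- a == "-" & b == "-"
  denom <- sum(!both_gap)
  if (denom == 0L) return(NA_real_)
  match <- sum(a != "-" & b != "-" & a == b)
  100 * match / denom
}

.msaCharMatrix <- function(msa) {
  do.call(rbind, strsplit(gappedRows(msa), ""))
}

#' Identity-percent vector to a reference species
#'
#' For every non-reference row of the alignment, percent identity to the
#' reference is computed from the already-aligned rows.  When a species
#' (or the reference) has several paralog rows, the species is collapsed to
#' its maximum identity over all row pairs, so each species contributes one
#' value.
#'
#' @param msa a [FamilyMSA-class].
#' @param referenceSpecies the species whose row(s) serve as reference.
#' @return Named numeric vector: species -> percent identity to the
#'   reference (the reference species itself is excluded).
#' @seealso [vectorCorrelation()] to correlate two such vectors.
#' @export
identityVector <- function(msa, referenceSpecies) {
  stopifnot(is(msa, "FamilyMSA"))
  sp <- msaSpecies(msa)
  refRows <- which(sp == referenceSpecies)
  if (!length(refRows))
    stop(sprintf("reference species '%s' not in alignment; available: %s",
                 referenceSpecies,
                 paste(sort(unique(sp)), collapse = ", ")), call. = FALSE)
  m <- .msaCharMatrix(msa)
  others <- sort(unique(sp[sp != referenceSpecies]))
  out <- vapply(others, function(s) {
    rows <- which(sp == s)
    max(vapply(rows, function(i) {
      max(vapply(refRows, function(r)
        .pairIdentityFromRows(m[i, ], m[r, ]), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  if (anyDuplicated(sp))
    cfLog("multiple paralog rows collapsed by maximum identity", "info")
  out
}

#' Correlate two species-keyed vectors
#'
#' Pearson correlation over the intersection of species keys; the
#' workhorse for comparing two families' identity-percent vectors.
#'
#' @param va,vb named numeric vectors keyed by species.
#' @param what label used in the result and in error messages.
#' @return A [CorrelationResult-class] (no p-value; `nPairs` = size of the
#'   intersection).
#' @examples
#' va <- c(human = 100, mouse = 50, cow = 25)
#' vb <- c(human = 100, mouse = 60, cow = 20)
#' vectorCorrelation(va, vb)
#' @export
vectorCorrelation <- function(va, vb, what = "identity-vector correlation") {
  common <- intersect(names(va), names(vb))
  if (length(common) < 3L)
    stop(sprintf("%s needs >= 3 shared species, got %d", what,
                 length(common)), call. = FALSE)
  r <- .pearson(va[common], vb[common], what)
  new("CorrelationResult", r = r, nPairs = as.numeric(length(common)),
      pValue = NA_real_, commonLabels = common, method = what,
      nPerm = NA_real_, seed = NA_real_)
}

#' Inter-species distance matrix from a family alignment
#'
#' Distance between two rows is `100 - identity_pct` computed on the
#' aligned rows.  Species with several paralog rows are collapsed to one
#' matrix entry by the mean distance over all row pairs (logged); the
#' diagonal is zero by construction.
#'
#' @param msa a [FamilyMSA-class] with at least 3 rows.
#' @param collapse `"mean"` (default) or `"min"` distance for
#'   multi-paralog species.
#' @return Symmetric numeric matrix with species labels, zero diagonal.
#' @seealso [mirrorCorrelation()], [patristicDistances()]
#' @export
msaDistanceMatrix <- function(msa, collapse = c("mean", "min")) {
  stopifnot(is(msa, "FamilyMSA"))
  collapse <- match.arg(collapse)
  if (msaRows(msa) < 3L)
    stop("need >= 3 alignment rows", call. = FALSE)
  m <- .msaCharMatrix(msa)
  sp <- msaSpecies(msa)
  species <- sort(unique(sp))
  k <- length(species)
  D <- matrix(0, k, k, dimnames = list(species, species))
  cfun <- if (collapse == "mean") mean else min
  if (anyDuplicated(sp))
    cfLog(sprintf("multi-paralog species collapsed by %s distance", collapse),
          "info")
  for (i in seq_len(k - 1L)) {
    ri <- which(sp == species[i])
    for (j in seq.int(i + 1L, k)) {
      rj <- which(sp == species[j])
      d <- outer(ri, rj, Vectorize(function(x, y)
        100 - .pairIdentityFromRows(m[x, ], m[y, ])))
      D[i, j] <- D[j, i] <- cfun(d)
    }
  }
  D
}

#' Read / write a labelled square distance matrix as TSV
#'
#' Row and column labels must agree; values must be symmetric with a zero
#' diagonal (validated on read).
#'
#' @param path TSV path (first column = row labels, header = column
#'   labels).
#' @return Numeric matrix with dimnames.
#' @export
readDistanceTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m)))
    stop("distance matrix row and column labels differ", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate labels in distance matrix", call. = FALSE)
  if (any(abs(m - t(m)) > 1e-8) || any(abs(diag(m)) > 1e-8) || any(m < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  m
}

#' @rdname readDistanceTsv
#' @param m labelled square matrix to write.
#' @export
writeDistanceTsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Patristic distance matrix from a newick tree
#'
#' Accepts a tree file or an `ape` `phylo` object and returns the matrix of
#' leaf-to-leaf path lengths, ready for [mirrorCorrelation()].
#'
#' @param tree a `phylo` object or path to a newick file.
#' @return Symmetric numeric matrix of patristic distances.
#' @export
patristicDistances <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  ape::cophenetic.phylo(tree)
}

.commonSubmatrices <- function(da, db) {
  common <- sort(intersect(rownames(da), rownames(db)))
  if (length(common) < 4L)
    stop(sprintf("mirror correlation needs >= 4 common labels, got %d",
                 length(common)), call. = FALSE)
  list(da = da[common, common, drop = FALSE],
       db = db[common, common, drop = FALSE],
       common = common)
}

.upperTri <- function(m) m[upper.tri(m)]

#' Mirror-tree correlation of two distance matrices
#'
#' Restricts both matrices to their common labels (identical order) and
#' computes the Pearson correlation over the upper-triangle off-diagonal
#' entries.  A high correlation means the two families' inter-species
#' divergence patterns mirror each other -- the co-evolution signal.
#'
#' @param da,db labelled symmetric distance matrices (species in
#'   `rownames`/`colnames`), e.g. from [msaDistanceMatrix()] or
#'   [patristicDistances()].
#' @return A [CorrelationResult-class]; `nPairs` = k(k-1)/2 for k common
#'   labels.
#' @seealso [mirrorPermutationPvalue()] for the permutation null.
#' @export
mirrorCorrelation <- function(da, db) {
  s <- .commonSubmatrices(da, db)
  r <- .pearson(.upperTri(s$da), .upperTri(s$db), "mirror correlation")
  new("CorrelationResult", r = r,
      nPairs = length(s$common) * (length(s$common) - 1) / 2,
      pValue = NA_real_, commonLabels = s$common,
      method = "mirror-tree correlation", nPerm = NA_real_,
      seed = NA_real_)
}

#' Permutation p-value for the mirror-tree correlation
#'
#' The null is generated by shuffling the species-label assignment of the
#' second matrix within the common label set (rows and columns permuted
#' together) and recomputing the correlation.  The add-one estimator
#' `(1 + #\{|r_perm| >= |r_obs|\}) / (1 + nPerm)` gives the two-sided
#' p-value; `alternative = "greater"` counts `r_perm >= r_obs` instead.
#'
#' @inheritParams mirrorCorrelation
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed (required).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return A [CorrelationResult-class] with the permutation p-value.
#' @export
mirrorPermutationPvalue <- function(da, db, nPerm = 999L, seed,
                                    alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  nPerm <- as.integer(nPerm)
  if (nPerm < 99L) stop("nPerm must be >= 99", call. = FALSE)
  if (missing(seed)) stop("seed is required for permutation tests",
                          call. = FALSE)
  s <- .commonSubmatrices(da, db)
  xa <- .upperTri(s$da)
  rObs <- .pearson(xa, .upperTri(s$db), "mirror correlation")
  k <- length(s$common)
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(nPerm), function(i) {
      p <- sample.int(k)
      rp <- stats::cor(xa, .upperTri(s$db[p, p, drop = FALSE]))
      if (alternative == "two.sided") abs(rp) >= abs(rObs) - 1e-9
      else rp >= rObs - 1e-9
    }, logical(1)))
  })
  new("CorrelationResult", r = rObs,
      nPairs = k * (k - 1) / 2, pValue = (1 + exceed) / (1 + nPerm),
      commonLabels = s$common,
      method = sprintf("mirror-tree correlation (%s permutation)",
                       alternative),
      nPerm = as.numeric(nPerm), seed = as.numeric(seed))
}

#' Exact mirror-tree permutation p-value by full enumeration
#'
#' Enumerates all k! label permutations of the second matrix (practical
#' for k <= 8) and returns the exact tail probability.  Oracle for the
#' Monte-Carlo estimate of [mirrorPermutationPvalue()].
#'
#' @inheritParams mirrorPermutationPvalue
#' @return List with `pValue` and `nArrangements` (= k!).
#' @export
exactMirrorPvalue <- function(da, db,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  s <- .commonSubmatrices(da, db)
  xa <- .upperTri(s$da)
  rObs <- .pearson(xa, .upperTri(s$db), "mirror correlation")
  k <- length(s$common)
  if (k > 8L) stop("exact enumeration limited to 8 common labels",
                   call. = FALSE)
  perms <- .allPermutations(k)
  hits <- vapply(perms, function(p) {
    rp <- stats::cor(xa, .upperTri(s$db[p, p, drop = FALSE]))
    if (alternative == "two.sided") abs(rp) >= abs(rObs) - 1e-9
    else rp >= rObs - 1e-9
  }, logical(1))
  list(pValue = mean(hits), nArrangements = length(perms))
}

.allPermutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- .allPermutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 0L
  for (p in sub) {
    for (pos in seq_len(k)) {
      idx <- idx + 1L
      out[[idx]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
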