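## Copy-number concordance: contingency construction from a species panel
## and independence testing (asymptotic Pearson chi-squared, and a
## permutation companion that is honest at the small sample sizes typical
## of species panels).

#' Read a copy-number panel from TSV
#'
#' Expects tab-separated columns `species`, `copies_a`, `copies_b`,
#' `complete_genome` (header required; `complete_genome` optional,
#' defaulting to `TRUE`).
#'
#' @param path path to the TSV file.
#' @param maxCopies validation upper bound on copy counts.
#' @return A [CopyNumberPanel-class].
#' @export
readCopyProfiles <- function(path, maxCopies = 10L) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("species", "copies_a", "copies_b")
  if (!all(need %in% names(df)))
    stop("copy-profile TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cg <- if ("complete_genome" %in% names(df))
    as.logical(df$complete_genome) else TRUE
  copyNumberPanel(df$species, df$copies_a, df$copies_b,
                  completeGenome = cg, maxCopies = maxCopies)
}

#' Write a copy-number panel to TSV
#'
#' @param panel a [CopyNumberPanel-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeCopyProfiles <- function(panel, path) {
  utils::write.table(panelAsDataFrame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Contingency table from two copy vectors: rows = levels of b, columns =
## levels of a, levels observed and ascending.  All-zero rows/columns cannot
## arise from observed levels but are dropped defensively.
.contingency <- function(a, b) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  tab <- table(factor(b, levels = lb), factor(a, levels = la))
  m <- matrix(as.integer(tab), nrow = length(lb), ncol = length(la),
              dimnames = list(copies_b = as.character(lb),
                              copies_a = as.character(la)))
  m <- m[rowSums(m) > 0L, colSums(m) > 0L, drop = FALSE]
  m
}

#' Build the copy-number contingency table of a panel
#'
#' Cross-tabulates species by the copy number of each family: rows are the
#' observed copy levels of family B, columns those of family A, both in
#' ascending order.  Cell (i, j) counts species with `copies_b` at row
#' level i and `copies_a` at column level j.
#'
#' @param panel a [CopyNumberPanel-class].
#' @return Integer matrix with `copies_b` levels as row names and
#'   `copies_a` levels as column names.  A single-row or single-column
#'   (degenerate) table is returned with a warning logged; the asymptotic
#'   test will refuse it.
#' @examples
#' panel <- copyNumberPanel(
#'   c("armadillo", "human", "chimp", "macaque", "guinea_pig",
#'     "mouse", "rat", "cow"),
#'   copiesA = c(0, 1, 1, 1, 1, 2, 2, 2),
#'   copiesB = c(1, 1, 1, 1, 1, 2, 2, 2))
#' contingencyFromProfiles(panel)
#' @export
contingencyFromProfiles <- function(panel) {
  stopifnot(is(panel, "CopyNumberPanel"))
  tab <- .contingency(panel@copiesA, panel@copiesB)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    cfLog("contingency table is degenerate (fewer than 2 rows or columns)",
          "warn")
  tab
}

## Pearson statistic from a contingency table; 0 for degenerate tables
## (observed == expected by construction).
.pearsonStat <- function(tab) {
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - E)^2 / E)
}

#' Pearson chi-squared test of copy-number independence
#'
#' The classical test of association between the two families' copy
#' numbers: `X^2 = sum (O - E)^2 / E` with expectations from the row and
#' column marginals, `df = (r - 1)(c - 1)`, upper-tail chi-squared p-value,
#' and no continuity correction.
#'
#' Species panels are small, so several expected counts typically fall
#' below 5 and the asymptotic p-value is approximate; the permutation
#' companion [permutationIndependence()] is recommended alongside it.
#'
#' @param table an integer contingency matrix, e.g. from
#'   [contingencyFromProfiles()].
#' @return An [IndependenceTest-class] with `method = "asymptotic"`.
#' @examples
#' tab <- matrix(c(1, 0, 4, 0, 0, 3), nrow = 2)
#' chiSquaredIndependence(tab)
#' @export
chiSquaredIndependence <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0))
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("degenerate contingency table (single row or column); ",
         "use permutationIndependence() on the panel instead",
         call. = FALSE)
  stat <- .pearsonStat(table)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  new("IndependenceTest", statistic = stat, df = as.numeric(df),
      pValue = p, method = "asymptotic", nPerm = NA_real_,
      table = table, seed = NA_real_)
}

#' Permutation test of copy-number independence
#'
#' Breaks the species-wise pairing by permuting the family-B copy vector
#' against family A, recomputing the Pearson statistic for each
#' permutation.  The p-value uses the add-one estimator
#' `(1 + #\{statistic_perm >= statistic_obs\}) / (1 + nPerm)`, which is
#' valid (never anti-conservative) for any number of permutations.
#'
#' @param panel a [CopyNumberPanel-class].
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed (required: permutation results must be
#'   reproducible).
#' @return An [IndependenceTest-class] with `method = "permutation"`.
#' @export
permutationIndependence <- function(panel, nPerm = 999L, seed) {
  stopifnot(is(panel, "CopyNumberPanel"))
  nPerm <- as.integer(nPerm)
  if (nPerm < 99L) stop("nPerm must be >= 99", call. = FALSE)
  if (missing(seed)) stop("seed is required for permutation tests",
                          call. = FALSE)
  a <- panel@copiesA; b <- panel@copiesB
  obs <- .pearsonStat(.contingency(a, b))
  ## hot path: integer-coded cross-tabulation via tabulate()
  ca <- match(a, sort(unique(a))); nA <- length(unique(a))
  cb0 <- match(b, sort(unique(b))); nB <- length(unique(b))
  permStat <- function(cb) {
    m <- matrix(tabulate(ca + nA * (cb - 1L), nA * nB), nA, nB)
    if (nA < 2L || nB < 2L) return(0)
    n <- sum(m)
    E <- outer(rowSums(m), colSums(m)) / n
    sum((m - E)^2 / E)
  }
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(nPerm), function(i) permStat(sample(cb0)),
               numeric(1)) >= obs - 1e-9)
  })
  p <- (1 + exceed) / (1 + nPerm)
  new("IndependenceTest", statistic = obs, df = NA_real_, pValue = p,
      method = "permutation", nPerm = as.numeric(nPerm),
      table = .contingency(a, b), seed = as.numeric(seed))
}

#' Exact permutation null by full enumeration
#'
#' Enumerates every distinguishable reordering of the family-B copy vector
#' (permutations of a multiset) and returns the exact probability that a
#' random pairing yields a Pearson statistic at least as large as the
#' observed one.  Used as the oracle against which the Monte-Carlo
#' permutation p-value is validated; practical when the number of
#' distinguishable permutations is at most a few tens of thousands.
#'
#' @param panel a [CopyNumberPanel-class].
#' @param maxArrangements refuse enumeration beyond this many
#'   distinguishable permutations.
#' @return List with `pValue` (exact tail probability, uniform over
#'   distinguishable arrangements weighted by multiplicity),
#'   `nArrangements`.
#' @export
exactPermutationPvalue <- function(panel, maxArrangements = 2e5) {
  stopifnot(is(panel, "CopyNumberPanel"))
  a <- panel@copiesA; b <- panel@copiesB
  obs <- .pearsonStat(.contingency(a, b))

  ## enumerate multiset permutations of b with multiplicities
  vals <- sort(unique(b))
  counts0 <- as.integer(table(factor(b, levels = vals)))
  n <- length(b)
  nArr <- factorial(n) / prod(factorial(counts0))
  if (nArr > maxArrangements)
    stop(sprintf("%.0f distinguishable permutations exceed the enumeration cap",
                 nArr), call. = FALSE)

  total <- 0; hit <- 0
  perm <- integer(n)
  recurse <- function(pos, counts, weight) {
    if (pos > n) {
      stat <- .pearsonStat(.contingency(a, vals[perm]))
      total <<- total + weight
      if (stat >= obs - 1e-9) hit <<- hit + weight
      return(invisible(NULL))
    }
    for (v in seq_along(vals)) {
      if (counts[v] == 0L) next
      perm[pos] <<- v
      counts[v] <- counts[v] - 1L
      recurse(pos + 1L, counts, weight)
      counts[v] <- counts[v] + 1L
    }
  }
  recurse(1L, counts0, 1)
  list(pValue = hit / total, nArrangements = nArr)
}

#' The eight-species eutherian copy-number panel
#'
#' The bundled example panel: copy numbers of the two studied families
#' across eight placental mammals (armadillo 0/1; human, chimpanzee,
#' macaque and guinea pig 1/1; mouse, rat and cow 2/2), as shipped in
#' `inst/extdata/eutheria_copy_number.tsv`.
#'
#' @return A [CopyNumberPanel-class] of 8 species.
#' @examples
#' contingencyFromProfiles(eutheriaPanel())
#' @export
eutheriaPanel <- function() {
  readCopyProfiles(system.file("extdata", "eutheria_copy_number.tsv",
                               package = "coevofam", mustWork = TRUE))
}
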