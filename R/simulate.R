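## Simulator of coupled two-family evolution along a species tree.
##
## The generative model: a Yule species tree; per-branch duplication events
## for family A (Bernoulli pDup) that family B reuses with probability
## kappa (else draws its own); per-copy losses (Bernoulli pLoss); lognormal
## branch-rate multipliers shared between families with the same kappa;
## residue substitution with per-site Poisson counts and uniform
## replacement over the other 19 residues (no indels, so rows are aligned
## by construction); and error-bearing reads drawn from paralog
## transcripts.  kappa = 0 gives independent evolution (type-I error
## studies); kappa = 1 gives fully coupled evolution (power studies).

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

#' Simulation configuration
#'
#' Bundles and validates the parameters of the coupled-evolution
#' generator.  The seed is mandatory: every generator is bit-reproducible
#' under a fixed seed.
#'
#' @param nSpecies number of species (>= 3); default 8, a typical
#'   copy-number panel size.
#' @param pDup per-branch duplication probability; default 0.08
#'   (duplications in a minority of lineages).
#' @param pLoss per-branch per-copy loss probability; default 0.02.
#' @param kappa coupling coefficient in `[0, 1]` shared by duplication
#'   events and branch-rate multipliers; default 1 (fully coupled).
#' @param seqLength protein length simulated; default 300 residues.
#' @param rateSigma lognormal sdlog of branch-rate multipliers; default
#'   0.5.
#' @param nReads,readLength,errorRate read-simulation parameters; defaults
#'   1000 reads of 60 nt at 0.5% per-base error.
#' @param meanBranch mean of the exponential branch lengths (expected
#'   substitutions/site); default 0.1.
#' @param seed RNG seed (required).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(nSpecies = 8L, pDup = 0.08, pLoss = 0.02, kappa = 1,
                      seqLength = 300L, rateSigma = 0.5,
                      nReads = 1000L, readLength = 60L, errorRate = 0.005,
                      meanBranch = 0.1, seed) {
  if (missing(seed)) stop("seed is required in simConfig()", call. = FALSE)
  cfg <- list(nSpecies = as.integer(nSpecies), pDup = pDup, pLoss = pLoss,
              kappa = kappa, seqLength = as.integer(seqLength),
              rateSigma = rateSigma, nReads = as.integer(nReads),
              readLength = as.integer(readLength), errorRate = errorRate,
              meanBranch = meanBranch, seed = as.integer(seed))
  with(cfg, {
    stopifnot(nSpecies >= 3L, seqLength >= 50L, rateSigma > 0,
              meanBranch > 0, readLength >= 1L, nReads >= 1L)
    for (p in c(pDup, pLoss, kappa, errorRate))
      if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  })
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", paste(names(x), unlist(x), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate a Yule species tree
#'
#' Topology by the forward Yule process (each split picks a uniform extant
#' lineage); branch lengths i.i.d. exponential with mean `meanBranch`
#' expected substitutions/site.
#'
#' @param nSpecies number of leaves (>= 3).
#' @param seed RNG seed; `NULL` uses (and advances) the current stream.
#' @param meanBranch mean branch length; default 0.1.
#' @return An `ape` `phylo` object with leaf names `s1 ... sN`.
#' @examples
#' tr <- simSpeciesTree(5, seed = 1)
#' ape::Ntip(tr)
#' @export
simSpeciesTree <- function(nSpecies, seed = NULL, meanBranch = 0.1) {
  stopifnot(nSpecies >= 3L)
  withSeed(seed, {
    tips <- c("s1", "s2")
    k <- 2L
    while (k < nSpecies) {
      i <- sample.int(length(tips), 1L)
      k <- k + 1L
      tips[i] <- sprintf("(%s,s%d)", tips[i], k)
    }
    tree <- ape::read.tree(text = sprintf("(%s,%s);", tips[1L],
                                          if (length(tips) > 1L) tips[2L] else "s2"))
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / meanBranch)
    tree
  })
}

## Edges of a phylo tree in root-to-leaf (preorder) order.
.preorderEdges <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  ord <- integer(0)
  stack <- root
  childEdges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  while (length(stack)) {
    node <- stack[[1L]]; stack <- stack[-1L]
    ed <- childEdges[[as.character(node)]]
    if (is.null(ed)) next
    ord <- c(ord, ed)
    stack <- c(tree$edge[ed, 2L], stack)
  }
  ord
}

#' Simulate coupled duplication/loss histories for two families
#'
#' Family A draws a duplication event on each branch with probability
#' `pDup`; family B reuses A's event indicator with probability `kappa`,
#' else draws its own.  A duplication doubles every extant copy of the
#' family; each copy is then lost independently with probability `pLoss`.
#' Leaf copy numbers are tallied into a [CopyNumberPanel-class].
#'
#' @param tree a `phylo` species tree, e.g. from [simSpeciesTree()].
#' @param config a [simConfig()].
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return List with `panel` (the [CopyNumberPanel-class]) and `truth`, a
#'   replayable record holding, per preorder branch and family, the event
#'   indicator and the per-copy survival mask, plus per-node copy counts.
#' @export
simCopyHistories <- function(tree, config, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "SimConfig"))
  withSeed(seed, {
    nTip <- ape::Ntip(tree)
    root <- nTip + 1L
    nNode <- max(tree$edge)
    copies <- matrix(NA_integer_, nNode, 2L,
                     dimnames = list(NULL, c("A", "B")))
    copies[root, ] <- 1L
    ord <- .preorderEdges(tree)
    events <- matrix(FALSE, nrow(tree$edge), 2L,
                     dimnames = list(NULL, c("A", "B")))
    survivors <- list(A = vector("list", nrow(tree$edge)),
                      B = vector("list", nrow(tree$edge)))
    for (e in ord) {
      parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      evA <- stats::runif(1) < config$pDup
      evB <- if (stats::runif(1) < config$kappa) evA
             else stats::runif(1) < config$pDup
      events[e, ] <- c(evA, evB)
      for (f in c("A", "B")) {
        k <- copies[parent, f]
        if (events[e, f]) k <- 2L * k
        surv <- stats::runif(k) >= config$pLoss
        survivors[[f]][[e]] <- surv
        copies[child, f] <- sum(surv)
      }
    }
    leafCopies <- copies[seq_len(nTip), , drop = FALSE]
    panel <- copyNumberPanel(tree$tip.label,
                             copiesA = leafCopies[, "A"],
                             copiesB = leafCopies[, "B"],
                             maxCopies = max(10L, leafCopies))
    list(panel = panel,
         truth = list(events = events, survivors = survivors,
                      copies = copies, preorder = ord))
  })
}

#' Simulate coupled branch-rate multipliers
#'
#' Family A gets lognormal(meanlog 0, sdlog `rateSigma`) multipliers per
#' branch; family B reuses A's multiplier on each branch with probability
#' `kappa`, else draws a fresh one.  Shared rate variation is what drives
#' the mirror-tree signal.
#'
#' @param tree a `phylo` species tree.
#' @param kappa coupling coefficient in `[0, 1]`.
#' @param rateSigma lognormal sdlog (> 0).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return List with numeric vectors `A` and `B` (one multiplier per edge)
#'   and the logical vector `shared`.
#' @export
simBranchRates <- function(tree, kappa, rateSigma, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), rateSigma > 0,
            kappa >= 0, kappa <= 1)
  withSeed(seed, {
    nE <- nrow(tree$edge)
    rA <- stats::rlnorm(nE, 0, rateSigma)
    shared <- stats::runif(nE) < kappa
    rB <- ifelse(shared, rA, stats::rlnorm(nE, 0, rateSigma))
    list(A = rA, B = rB, shared = shared)
  })
}

## Apply k >= 0 substitution events per site, each replacing the residue by
## a uniform draw from the other 19.
.substitute <- function(seqChars, k) {
  while (any(k > 0L)) {
    idx <- which(k > 0L)
    cur <- match(seqChars[idx], .AA20)
    draw <- sample.int(19L, length(idx), replace = TRUE)
    seqChars[idx] <- .AA20[ifelse(draw >= cur, draw + 1L, draw)]
    k[idx] <- k[idx] - 1L
  }
  seqChars
}

#' Simulate a family alignment along the species tree
#'
#' Replays the duplication/loss history of one family (from
#' [simCopyHistories()]) while evolving sequences: the root sequence is
#' uniform over the 20 residues; along each branch every site accumulates
#' a Poisson(branch length x rate multiplier) number of substitution
#' events, each replacing the residue uniformly by one of the other 19.
#' Duplications copy the current sequence; there are no indels, so rows
#' align trivially.  Rows of multi-copy species are ided
#' `species_p<i>` with paralog tag `p<i>`.
#'
#' @param tree a `phylo` species tree.
#' @param truth the `truth` component returned by [simCopyHistories()].
#' @param config a [simConfig()].
#' @param rates per-edge rate multipliers for this family (numeric; e.g.
#'   `simBranchRates(...)$A`); default all 1.
#' @param family family label used in row ids (`"A"` or `"B"`).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A [FamilyMSA-class].
#' @export
simAlignment <- function(tree, truth, config, rates = NULL,
                         family = c("A", "B"), seed = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(tree, "phylo"), inherits(config, "SimConfig"))
  nE <- nrow(tree$edge)
  if (is.null(rates)) rates <- rep(1, nE)
  stopifnot(length(rates) == nE)
  withSeed(seed, {
    nTip <- ape::Ntip(tree)
    root <- nTip + 1L
    L <- config$seqLength
    seqsAtNode <- vector("list", max(tree$edge))
    seqsAtNode[[root]] <- list(sample(.AA20, L, replace = TRUE))
    for (e in truth$preorder) {
      parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      cp <- seqsAtNode[[parent]]
      if (truth$events[e, family]) cp <- c(cp, cp)
      cp <- cp[truth$survivors[[family]][[e]]]
      d <- tree$edge.length[e] * rates[e]
      cp <- lapply(cp, function(s) .substitute(s, stats::rpois(L, d)))
      seqsAtNode[[child]] <- cp
    }
    rows <- character(0); species <- character(0); paralog <- character(0)
    for (i in seq_len(nTip)) {
      cp <- seqsAtNode[[i]]
      if (!length(cp)) next
      for (j in seq_along(cp)) {
        tag <- if (length(cp) > 1L) sprintf("p%d", j) else NA_character_
        id <- if (is.na(tag)) tree$tip.label[i]
              else paste(tree$tip.label[i], tag, sep = "_")
        rows[id] <- paste(cp[[j]], collapse = "")
        species <- c(species, tree$tip.label[i])
        paralog <- c(paralog, tag)
      }
    }
    familyMSA(rows, species = species, paralog = paralog,
              family = paste0("sim", family))
  })
}

#' Simulate error-bearing reads from transcripts
#'
#' Reads start at uniform positions, and each base is replaced by a
#' uniform different base with probability `errorRate`.  The true source
#' transcript of every read is recorded.
#'
#' @param transcripts named `DNAStringSet` or named character vector.
#' @param nReads number of reads.
#' @param readLength read length (must not exceed the shortest
#'   transcript).
#' @param errorRate per-base error probability.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param weights optional sampling weights per transcript (relative
#'   abundances); default uniform.
#' @return List with `reads` (named character vector `read_1 ...`) and
#'   `truth` (data.frame `read_id`, `source`, `start`).
#' @export
simReads <- function(transcripts, nReads = 1000L, readLength = 60L,
                     errorRate = 0.005, seed = NULL, weights = NULL) {
  tx <- if (is.character(transcripts)) transcripts
        else stats::setNames(as.character(transcripts), names(transcripts))
  if (is.null(names(tx))) stop("transcripts must be named", call. = FALSE)
  if (readLength > min(nchar(tx)))
    stop("readLength exceeds the shortest transcript", call. = FALSE)
  DNA <- c("A", "C", "G", "T")
  withSeed(seed, {
    src <- sample(names(tx), nReads, replace = TRUE, prob = weights)
    starts <- vapply(src, function(s)
      sample.int(nchar(tx[s]) - readLength + 1L, 1L), integer(1))
    reads <- vapply(seq_len(nReads), function(i) {
      r <- strsplit(substr(tx[src[i]], starts[i],
                           starts[i] + readLength - 1L), "")[[1]]
      err <- which(stats::runif(readLength) < errorRate)
      if (length(err)) {
        cur <- match(r[err], DNA)
        draw <- sample.int(3L, length(err), replace = TRUE)
        r[err] <- DNA[ifelse(draw >= cur, draw + 1L, draw)]
      }
      paste(r, collapse = "")
    }, character(1))
    names(reads) <- sprintf("read_%d", seq_len(nReads))
    list(reads = reads,
         truth = data.frame(read_id = names(reads), source = unname(src),
                            start = unname(starts),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate diverged paralog transcripts
#'
#' A random base transcript plus paralogs derived from it by substituting
#' a fixed fraction of positions (distinct sites, uniform alternative
#' base) -- the substrate for read-assignment accuracy studies at
#' controlled divergence.
#'
#' @param length transcript length (nt).
#' @param divergence fraction of substituted positions in each derived
#'   paralog (0 gives identical duplicates).
#' @param nParalogs number of transcripts (>= 2); the first is the base.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return Named character vector `t1 ... tK`.
#' @export
simDivergedTranscripts <- function(length = 1000L, divergence = 0.1,
                                   nParalogs = 2L, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 1, nParalogs >= 2L)
  DNA <- c("A", "C", "G", "T")
  withSeed(seed, {
    base <- sample(DNA, length, replace = TRUE)
    out <- list(t1 = base)
    nSub <- round(divergence * length)
    for (k in seq.int(2L, nParalogs)) {
      der <- base
      if (nSub > 0L) {
        pos <- sample.int(length, nSub)
        cur <- match(der[pos], DNA)
        draw <- sample.int(3L, nSub, replace = TRUE)
        der[pos] <- DNA[ifelse(draw >= cur, draw + 1L, draw)]
      }
      out[[sprintf("t%d", k)]] <- der
    }
    vapply(out, paste, character(1), collapse = "")
  })
}

#' One replicate of the full coupled-evolution generator
#'
#' Convenience wrapper chaining [simSpeciesTree()], [simCopyHistories()],
#' [simBranchRates()] and [simAlignment()] for both families under a
#' single seed, so a pipeline run is one call.
#'
#' @param config a [simConfig()]; its `seed` drives all randomness.
#' @return List with `tree`, `panel`, `truth`, `rates`, `msaA`, `msaB`.
#' @export
simCoupledFamilies <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed, {
    tree <- simSpeciesTree(config$nSpecies, seed = NULL,
                           meanBranch = config$meanBranch)
    hist <- simCopyHistories(tree, config, seed = NULL)
    rates <- simBranchRates(tree, config$kappa, config$rateSigma,
                            seed = NULL)
    msaA <- simAlignment(tree, hist$truth, config, rates$A, family = "A",
                         seed = NULL)
    msaB <- simAlignment(tree, hist$truth, config, rates$B, family = "B",
                         seed = NULL)
    list(tree = tree, panel = hist$panel, truth = hist$truth,
         rates = rates, msaA = msaA, msaB = msaB)
  })
}
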