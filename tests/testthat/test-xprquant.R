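twoTxMeta <- function() {
  data.frame(transcript_id = c("tA", "tB"), gene = c("gA", "gB"),
             paralog = c("a", "b"), length_nt = c(1000L, 1200L),
             stringsAsFactors = FALSE)
}

test_that("best-score assignment separates unique, tied and unmapped reads", {
  tab <- data.frame(
    read_id = c("r1", "r1", "r2", "r2", "r3", "r3"),
    transcript_id = rep(c("tA", "tB"), 3),
    score = c(100, 90, 95, 95, 10, 12))
  asg <- assignBestScore(tab, twoTxMeta(), minScore = 50)
  expect_equal(assignedReads(asg), c(r1 = "tA"))
  expect_equal(discardedExAequo(asg), "r2")
  expect_equal(discardedUnmapped(asg), "r3")

  ## partition property: every read lands in exactly one bucket
  expect_setequal(c(names(assignedReads(asg)), discardedExAequo(asg),
                    discardedUnmapped(asg)), unique(tab$read_id))

  ## missing metadata is an error
  expect_error(assignBestScore(
    data.frame(read_id = "r", transcript_id = "ghost", score = 1),
    twoTxMeta(), minScore = 0), "ghost")
})

test_that("assignment is order-independent and monotone in the threshold", {
  set.seed(61)
  tab <- data.frame(
    read_id = rep(sprintf("r%02d", 1:30), each = 2),
    transcript_id = rep(c("tA", "tB"), 30),
    score = round(runif(60, 0, 100), 2))
  a1 <- assignBestScore(tab, twoTxMeta(), minScore = 20)
  a2 <- assignBestScore(tab[sample(nrow(tab)), ], twoTxMeta(), minScore = 20)
  expect_identical(assignedReads(a1), assignedReads(a2))
  expect_identical(sort(discardedExAequo(a1)), sort(discardedExAequo(a2)))

  nAssigned <- vapply(c(0, 20, 50, 80, 101), function(ms)
    length(assignedReads(assignBestScore(tab, twoTxMeta(), ms))),
    integer(1))
  expect_true(all(diff(nAssigned) <= 0))

  ## near-equal scores within 1e-6 count as ties
  tie <- data.frame(read_id = c("r", "r"), transcript_id = c("tA", "tB"),
                    score = c(50, 50 + 1e-8))
  expect_equal(discardedExAequo(assignBestScore(tie, twoTxMeta(), 0)), "r")
})

test_that("counts respect gene structure and conservation", {
  meta <- data.frame(transcript_id = c("t1", "t2", "t3"),
                     gene = c("g", "g", "h"), paralog = c("a", "b", "a"),
                     length_nt = c(500L, 600L, 700L))
  tab <- data.frame(read_id = c("r1", "r2", "r3"),
                    transcript_id = c("t1", "t2", "t1"),
                    score = c(9, 9, 9))
  asg <- assignBestScore(tab, meta, minScore = 1)
  cnt <- countAssigned(asg, meta)
  expect_equal(unname(cnt$perGene["g"]), 3L)
  expect_equal(unname(cnt$perGene["h"]), 0L)
  expect_equal(sum(cnt$perTranscript), length(assignedReads(asg)))

  empty <- assignBestScore(tab[0, ], meta, minScore = 1)
  expect_true(all(countAssigned(empty, meta)$perTranscript == 0L))
})

test_that("RPKM follows its closed formula", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(37, 1537, 28314662), 37 * 1e9 / (1537 * 28314662))
  expect_equal(rpkm(37, 1537, 28314662), 0.850190944386, tolerance = 1e-10)
  expect_error(rpkm(1, 0, 100), "length")
  expect_error(rpkm(1, 100, 0), "total")
})

test_that("expression profiles and correlations behave", {
  counts <- matrix(c(10, 2, 8, 4, 6, 6, 4, 8, 2, 10), nrow = 2,
                   dimnames = list(c("gA", "gB"), sprintf("s%d", 1:5)))
  prof <- expressionProfile(counts, geneLength = c(gA = 1000, gB = 1000),
                            totalMapped = rep(1e6, 5))
  expect_equal(rpkmMatrix(prof)["gA", "s1"], rpkm(10, 1000, 1e6))

  ## gB = 12 - gA: exact anti-correlation
  expect_equal(expressionCorrelation(prof, "gA", "gB")@r, -1)
  expect_equal(expressionCorrelation(prof, "gA", "gA")@r, 1)

  counts2 <- matrix(c(10, 1, 8, 2, 6, 3, 4, 5, 2, 9), nrow = 2,
                    dimnames = list(c("gA", "gB"), sprintf("s%d", 1:5)))
  prof2 <- expressionProfile(counts2, c(gA = 1000, gB = 1000),
                             rep(1e6, 5))
  cr <- expressionCorrelation(prof2, "gA", "gB")
  expect_equal(cr@r, oraclePearson(c(10, 8, 6, 4, 2), c(1, 2, 3, 5, 9)))
  expect_equal(cr@r, -0.95)

  flat <- expressionProfile(matrix(c(1, 1, 1, 1, 1, 1), nrow = 2,
                                   dimnames = list(c("gA", "gB"), NULL)),
                            c(gA = 1, gB = 1), rep(1, 3))
  expect_error(expressionCorrelation(flat, "gA", "gB"), "constant")
  expect_error(expressionCorrelation(prof, "gA", "nope"), "nope")
})

test_that("simulated reads from distinct paralogs are assigned accurately", {
  tx <- simDivergedTranscripts(length = 600, divergence = 0.2, seed = 71)
  rd <- simReads(tx, nReads = 200, readLength = 60, errorRate = 0,
                 seed = 72)
  scores <- scoreReads(rd$reads, tx)
  asg <- assignBestScore(scores, data.frame(
    transcript_id = names(tx), gene = "g", paralog = names(tx),
    length_nt = nchar(tx)), minScore = 30)
  truth <- stats::setNames(rd$truth$source, rd$truth$read_id)
  acc <- mean(assignedReads(asg) == truth[names(assignedReads(asg))])
  expect_equal(acc, 1)  # error-free reads at 20% divergence: exact matches

  ## identical duplicate transcripts force ties for every read
  dup <- simDivergedTranscripts(length = 600, divergence = 0, seed = 73)
  rdd <- simReads(dup, nReads = 100, readLength = 60, errorRate = 0.01,
                  seed = 74)
  asgd <- assignBestScore(scoreReads(rdd$reads, dup), data.frame(
    transcript_id = names(dup), gene = "g", paralog = names(dup),
    length_nt = nchar(dup)), minScore = 30)
  expect_length(discardedExAequo(asgd), 100L)
  expect_length(assignedReads(asgd), 0L)
})
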