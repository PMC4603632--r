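test_that("FASTA round trip preserves ids, residues and metadata", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1|Homo_sapiens", "MCP",
               ">s2|Mus_musculus|p1", "MCPA", ""), tf)
  seqs <- readFastaSeqs(tf)
  expect_equal(names(seqs), c("s1", "s2"))
  expect_equal(as.character(seqs), c(s1 = "MCP", s2 = "MCPA"))
  expect_equal(S4Vectors::mcols(seqs)$species,
               c("Homo_sapiens", "Mus_musculus"))
  expect_equal(S4Vectors::mcols(seqs)$paralog, c(NA, "p1"))

  tf2 <- withr::local_tempfile(fileext = ".fa")
  writeFastaSeqs(seqs, tf2)
  back <- readFastaSeqs(tf2)
  expect_equal(as.character(back), as.character(seqs))
  expect_equal(S4Vectors::mcols(back)$species,
               S4Vectors::mcols(seqs)$species)

  ## species defaults to id when the header has no pipe fields
  tf3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">plain", "MW"), tf3)
  expect_equal(S4Vectors::mcols(readFastaSeqs(tf3))$species, "plain")
})

test_that("malformed and empty FASTA are handled explicitly", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ok", "MCP", ">broken", ">next", "MW"), tf)
  expect_error(readFastaSeqs(tf), "line 3")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_length(readFastaSeqs(empty), 0L)

  gapped <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g", "MC-P"), gapped)
  expect_error(readFastaSeqs(gapped), "gap")
  expect_s4_class(readFamilyMSA(gapped), "FamilyMSA")
})

test_that("self-alignment is 100% identical and scores the diagonal sum", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  for (s in c("MCP", "HEAGAWGHEE", "WWKLV")) {
    pa <- alignPair(s, s)
    expect_equal(identityPct(pa), 100)
    expect_equal(similarityPct(pa), 100)
    chars <- strsplit(s, "")[[1]]
    expect_equal(alignmentScore(pa),
                 sum(e$BLOSUM62[cbind(chars, chars)]))
    pl <- localAlign(s, s)
    expect_equal(identityPct(pl), 100)
  }
})

test_that("identity and similarity are symmetric in argument order", {
  set.seed(11)
  for (i in 1:5) {
    a <- randSeq(sample(5:12, 1), c("A", "C", "D", "E", "W"))
    b <- randSeq(sample(5:12, 1), c("A", "C", "D", "E", "W"))
    pg1 <- alignPair(a, b); pg2 <- alignPair(b, a)
    expect_equal(identityPct(pg1), identityPct(pg2))
    expect_equal(similarityPct(pg1), similarityPct(pg2))
    expect_equal(alignmentScore(pg1), alignmentScore(pg2))
    ## local mode: the optimal score is symmetric; the reported segment
    ## (hence its identity) is tie-break-dependent when optima tie
    expect_equal(alignmentScore(localAlign(a, b)),
                 alignmentScore(localAlign(b, a)))
  }
})

test_that("local alignment floors at zero and targets the conserved block", {
  ## disjoint single residues with a negative pair score
  pa <- localAlign("W", "P")
  expect_equal(alignmentScore(pa), 0)
  expect_equal(nchar(alignedStrings(pa)[["a"]]), 0L)

  ## the WWW block dominates the local alignment
  pb <- localAlign("AAAWWWAAA", "CCCWWWCCC")
  expect_true(grepl("WWW", alignedStrings(pb)[["a"]]))
  expect_equal(alignmentScore(pb), oracleLocalScore(
    "AAAWWWAAA", "CCCWWWCCC", toyMatrix(c("A", "C", "W")), 10, 0.5))
})

test_that("alignment input validation rejects bad penalties and residues", {
  expect_error(alignPair("MC", "MC", gapOpening = 0.2, gapExtension = 0.5),
               "gapOpening")
  expect_error(alignPair("MC1", "MC"), "alphabet")
})

test_that("column conservation flags invariant gap-free columns only", {
  msa <- familyMSA(c(r1 = "MC-", r2 = "MCA"), species = c("s1", "s2"))
  cons <- columnConservation(msa)
  expect_equal(cons$is_invariant, c(TRUE, TRUE, FALSE))
  expect_equal(cons$residue, c("M", "C", NA))
  expect_equal(cons$gap_count, c(0L, 0L, 1L))

  ## single row: every non-gap column is invariant
  one <- columnConservation(familyMSA(c(r = "MA-C"), species = "s"))
  expect_equal(one$is_invariant, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("planted invariant cysteine columns are recovered exactly", {
  set.seed(21)
  n <- 10; L <- 50
  planted <- c(5L, 17L, 29L, 43L)
  nonCys <- c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L")
  rows <- replicate(n, sample(nonCys, L, replace = TRUE), simplify = FALSE)
  rows <- lapply(rows, function(r) { r[planted] <- "C"; paste(r, collapse = "") })
  names(rows) <- sprintf("r%d", seq_len(n))
  msa <- familyMSA(unlist(rows), species = sprintf("sp%d", seq_len(n)))
  cons <- columnConservation(msa)
  invC <- cons$column[cons$is_invariant & cons$residue == "C"]
  expect_equal(invC, planted)
  expect_equal(unname(invariantResidueCounts(cons)["C"]), 4L)
})

test_that("motif scanning matches the exhaustive window oracle", {
  expect_equal(scanMotif("ACFACY", "C-X-X-C"), 2L)
  expect_equal(as.integer(scanMotif("MCFACY", "C-F-[AT]-C-[FY]")), 2L)
  hit <- scanMotif("MCFACY", motifPattern("C-F-[AT]-C-[FY]", anchor = 2))
  expect_true(attr(hit, "anchor_matched"))

  ## overlapping matches are all reported
  expect_equal(scanMotif("CACAC", "C-X-C"), c(1L, 3L))

  set.seed(31)
  pat <- motifPattern("C-X-[AG]-C")
  for (i in 1:20) {
    s <- randSeq(sample(4:30, 1), c("A", "C", "G", "T", "W"))
    expect_equal(as.integer(scanMotif(s, pat)),
                 oracleMotifScan(s, pat$elements, pat$wildcard))
  }
  ## pattern longer than sequence: no match
  expect_length(scanMotif("CA", "C-X-X-C"), 0L)
})

test_that("interval masking is bounded, length-preserving and idempotent", {
  expect_equal(maskIntervals("ACGTACGT", data.frame(start = 3, end = 4)),
               "ACNNACGT")
  expect_equal(maskIntervals("ACGT", data.frame(start = integer(0),
                                                end = integer(0))), "ACGT")
  expect_equal(maskIntervals("ACGT", data.frame(start = 1, end = 4)), "NNNN")
  expect_equal(maskIntervals("MCPW", data.frame(start = 2, end = 3),
                             molecule = "protein"), "MXXW")
  once <- maskIntervals("ACGTACGT", data.frame(start = c(2, 5),
                                               end = c(3, 7)))
  expect_equal(maskIntervals(once, data.frame(start = c(2, 5),
                                              end = c(3, 7))), once)
  expect_error(maskIntervals("ACGT", data.frame(start = 2, end = 9)),
               "bounds")
})

test_that("interval TSV reader enforces 1-based inclusive sanity", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx1\t3\t4", "tx1\t7\t7"), tf)
  iv <- readIntervalTsv(tf)
  expect_equal(iv$start, c(3L, 7L))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("tx1\t5\t2", bad)
  expect_error(readIntervalTsv(bad), "start > end")
})
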