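eutherianLikePanel <- function() {
  copyNumberPanel(
    c("armadillo", "human", "chimp", "macaque", "guinea_pig",
      "mouse", "rat", "cow"),
    copiesA = c(0, 1, 1, 1, 1, 2, 2, 2),
    copiesB = c(1, 1, 1, 1, 1, 2, 2, 2))
}

test_that("contingency construction reproduces the 8-species table", {
  tab <- contingencyFromProfiles(eutherianLikePanel())
  expect_equal(unname(tab), matrix(c(1L, 0L, 4L, 0L, 0L, 3L), nrow = 2))
  expect_equal(rownames(tab), c("1", "2"))
  expect_equal(colnames(tab), c("0", "1", "2"))
  expect_equal(sum(tab), 8L)
})

test_that("degenerate panels collapse to 1x1 tables and are refused by chi2", {
  one <- copyNumberPanel("only", 1, 1)
  expect_warning(tab1 <- contingencyFromProfiles(one), NA)  # logged, not warned
  expect_equal(dim(tab1), c(1L, 1L))
  same <- copyNumberPanel(c("a", "b", "c"), c(2, 2, 2), c(1, 1, 1))
  expect_equal(dim(contingencyFromProfiles(same)), c(1L, 1L))
  expect_error(chiSquaredIndependence(contingencyFromProfiles(same)),
               "permutation")
})

test_that("Pearson chi-squared matches the formula oracle and chisq.test", {
  tab <- contingencyFromProfiles(eutherianLikePanel())
  res <- chiSquaredIndependence(tab)
  expect_equal(res@statistic, 8)
  expect_equal(res@df, 2)
  expect_equal(round(res@pValue, 3), 0.018)
  expect_equal(res@statistic, oracleChi2(tab))

  ## proportional rows: perfect independence
  prop <- chiSquaredIndependence(matrix(c(2, 1, 4, 2), nrow = 2))
  expect_equal(prop@statistic, 0)
  expect_equal(prop@pValue, 1)

  ## 100 random tables against the hand oracle and the reference
  ## implementation (no continuity correction)
  set.seed(41)
  for (i in 1:100) {
    m <- matrix(rpois(6, 5) + 1L, nrow = sample(2:3, 1))
    r <- chiSquaredIndependence(m)
    expect_equal(r@statistic, oracleChi2(m), tolerance = 1e-10)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(r@statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r@pValue, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("permutation independence test is seeded, valid and enumerable", {
  ## perfectly coupled two-level panel: strong rejection
  coupled <- copyNumberPanel(sprintf("s%d", 1:8),
                             c(1, 1, 1, 1, 2, 2, 2, 2),
                             c(1, 1, 1, 1, 2, 2, 2, 2))
  p <- permutationIndependence(coupled, nPerm = 999, seed = 5)@pValue
  expect_lte(p, 0.05)
  ex <- exactPermutationPvalue(coupled)
  expect_equal(ex$nArrangements, choose(8, 4))
  expect_equal(ex$pValue, 2 / choose(8, 4))  # only the two perfect pairings

  ## constant family B: statistic invariant, p = 1
  const <- copyNumberPanel(letters[1:6], c(1, 2, 1, 2, 1, 2), rep(1, 6))
  expect_equal(permutationIndependence(const, nPerm = 99,
                                       seed = 1)@pValue, 1)

  ## reproducibility under a fixed seed
  p1 <- permutationIndependence(coupled, nPerm = 199, seed = 7)@pValue
  p2 <- permutationIndependence(coupled, nPerm = 199, seed = 7)@pValue
  expect_identical(p1, p2)

  ## Monte-Carlo estimate close to full enumeration on the 8-species panel
  exact <- exactPermutationPvalue(eutherianLikePanel())$pValue
  mc <- permutationIndependence(eutherianLikePanel(), nPerm = 4999,
                                seed = 11)@pValue
  expect_lt(abs(mc - exact), 4 * sqrt(exact * (1 - exact) / 4999) + 1e-3)
})

test_that("identity vectors collapse paralogs and respect the MSA", {
  msa <- familyMSA(c(h = "ACDE", m = "ACDF", c = "AGGG"),
                   species = c("human", "mouse", "cow"))
  v <- identityVector(msa, "human")
  expect_equal(v, c(cow = 25, mouse = 75))

  ## all rows equal to the reference
  same <- familyMSA(c(a = "MCW", b = "MCW", c = "MCW"),
                    species = c("x", "y", "z"))
  expect_true(all(identityVector(same, "x") == 100))

  ## paralogs collapse by maximum identity
  par <- familyMSA(c(h = "AAAA", m1 = "AAAT", m2 = "TTTT"),
                   species = c("human", "mouse", "mouse"),
                   paralog = c(NA, "p1", "p2"))
  expect_equal(identityVector(par, "human"), c(mouse = 75))

  expect_error(identityVector(msa, "yeti"), "human")
})

test_that("vector correlation follows the hand Pearson formula", {
  va <- c(s1 = 100, s2 = 50, s3 = 25)
  expect_equal(vectorCorrelation(va, va)@r, 1)
  expect_equal(vectorCorrelation(va, 100 - va)@r, -1)
  vb <- c(s1 = 100, s2 = 60, s3 = 20)
  cr <- vectorCorrelation(va, vb)
  expect_equal(cr@r, oraclePearson(va, vb))
  expect_equal(cr@r, 0.981980506062, tolerance = 1e-9)
  expect_equal(cr@nPairs, 3)
  expect_error(vectorCorrelation(va[1:2], vb[1:2]), "3 shared")
})

test_that("MSA distance matrices are symmetric with hand-checked entries", {
  msa <- familyMSA(c(h = "ACDE", m = "ACDF", c = "AGGG"),
                   species = c("human", "mouse", "cow"))
  D <- msaDistanceMatrix(msa)
  expect_equal(D["human", "mouse"], 25)
  expect_equal(D["human", "cow"], 75)
  expect_equal(D["mouse", "cow"], 75)   # ACDF vs AGGG: 1/4 identical
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))

  ident <- familyMSA(c(a = "MCW", b = "MCW", c = "MCW"),
                     species = c("x", "y", "z"))
  expect_true(all(msaDistanceMatrix(ident) == 0))
})

test_that("mirror correlation is invariant to label order and affine maps", {
  labs <- c("a", "b", "c", "d")
  da <- matrix(0, 4, 4, dimnames = list(labs, labs))
  da[upper.tri(da)] <- c(1, 2, 3, 4, 5, 6)
  da <- da + t(da)
  db2 <- 2 * da + 5; diag(db2) <- 0
  expect_equal(mirrorCorrelation(da, da)@r, 1)
  expect_equal(mirrorCorrelation(da, db2)@r, 1)

  ## reversed upper triangle: hand Pearson gives exactly -1
  dr <- matrix(0, 4, 4, dimnames = list(labs, labs))
  dr[upper.tri(dr)] <- c(6, 5, 4, 3, 2, 1)
  dr <- dr + t(dr)
  expect_equal(mirrorCorrelation(da, dr)@r,
               oraclePearson(c(1, 2, 3, 4, 5, 6), c(6, 5, 4, 3, 2, 1)))

  ## shuffling db's label order leaves r unchanged
  sh <- sample(labs)
  expect_equal(mirrorCorrelation(da, db2[sh, sh])@r, 1)

  expect_equal(mirrorCorrelation(da, da)@nPairs, 6)
  expect_error(mirrorCorrelation(da[1:3, 1:3], da[1:3, 1:3]), "4 common")
})

test_that("mirror permutation p-value agrees with exact enumeration", {
  set.seed(51)
  labs <- sprintf("s%d", 1:5)
  mk <- function() {
    m <- matrix(0, 5, 5, dimnames = list(labs, labs))
    m[upper.tri(m)] <- runif(10, 1, 100)
    m + t(m)
  }
  da <- mk(); db <- mk()
  ex <- exactMirrorPvalue(da, db)
  expect_equal(ex$nArrangements, 120)
  mc <- mirrorPermutationPvalue(da, db, nPerm = 1999, seed = 3)
  tol <- 4 * sqrt(ex$pValue * (1 - ex$pValue) / 1999) + 1e-3
  expect_lt(abs(mc@pValue - ex$pValue), tol)

  ## identical structured matrices: small p at 999 permutations
  labs8 <- sprintf("t%d", 1:8)
  d8 <- matrix(0, 8, 8, dimnames = list(labs8, labs8))
  d8[upper.tri(d8)] <- seq_len(28)
  d8 <- d8 + t(d8)
  self <- mirrorPermutationPvalue(d8, d8, nPerm = 999, seed = 9)
  expect_equal(self@r, 1)
  expect_lte(self@pValue, 0.01)
})

test_that("distance TSV and newick inputs feed the mirror statistic", {
  tr <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
  D <- patristicDistances(tr)
  expect_equal(D["a", "b"], 2)
  expect_equal(D["a", "c"], 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceTsv(D, tf)
  back <- readDistanceTsv(tf)
  expect_equal(back, D[rownames(back), colnames(back)])
  expect_equal(mirrorCorrelation(D, back)@r, 1)
})
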