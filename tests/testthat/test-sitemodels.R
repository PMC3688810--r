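# Unit-level checks of the codon-model machinery; the heavier
# parameter-recovery and calibration simulations live in the acceptance
# suite.

test_that("transition matrices are proper stochastic matrices", {
  type <- ampliMHC:::codonPairType()
  pi <- rep(1 / 61, 61)
  P <- ampliMHC:::codon_pmat(type, pi, 2, 0.5, 0.3)
  expect_equal(dim(P), c(61, 61))
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-10)
  # t = 0 gives identity; large t approaches the stationary distribution
  P0 <- ampliMHC:::codon_pmat(type, pi, 2, 0.5, 0)
  expect_equal(P0, diag(61), tolerance = 1e-10)
  Pinf <- ampliMHC:::codon_pmat(type, pi, 2, 0.5, 500)
  expect_equal(unname(Pinf[1, ]), pi, tolerance = 1e-8)
})

test_that("likelihood is invariant to taxon order and rerooting", {
  set.seed(5)
  tr <- ape::rcoal(8)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 2
  sim <- simulateCodonAlignment(tr, 30, omegas = 0.5, seed = 6)
  po <- ampliMHC:::.postorderEdges(tr)
  states <- ampliMHC:::.tipStates(sim$aln, po$tip.label)
  pi <- rep(1 / 61, 61)
  l1 <- sum(ampliMHC:::.classLogLik(states, po, 1, pi, 2, 1))
  # shuffle taxa
  shuf <- sample(seq_len(nrow(codonMatrix(sim$aln))))
  aln2 <- codonAlignment(setNames(
    apply(codonMatrix(sim$aln)[shuf, ], 1, paste, collapse = ""),
    rownames(codonMatrix(sim$aln))[shuf]))
  l2 <- sum(ampliMHC:::.classLogLik(
    ampliMHC:::.tipStates(aln2, po$tip.label), po, 1, pi, 2, 1))
  expect_equal(l1, l2, tolerance = 1e-6)
  # reroot
  tr2 <- ape::root(tr, outgroup = tr$tip.label[3], resolve.root = FALSE)
  po2 <- ampliMHC:::.postorderEdges(tr2)
  l3 <- sum(ampliMHC:::.classLogLik(
    ampliMHC:::.tipStates(sim$aln, po2$tip.label), po2, 1, pi, 2, 1))
  expect_equal(l1, l3, tolerance = 1e-6)
})

test_that("M8 at p1 -> 0 reproduces the M7 likelihood", {
  set.seed(9)
  tr <- ape::rcoal(6)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 2
  sim <- simulateCodonAlignment(tr, 40, omegas = 0.4, seed = 10)
  po <- ampliMHC:::.postorderEdges(tr)
  states <- ampliMHC:::.tipStates(sim$aln, po$tip.label)
  pi <- codonFreqF3x4(codonMatrix(sim$aln))
  shapes <- c(0.4, 0.6)
  om7 <- ampliMHC:::.beta_classes(shapes[1], shapes[2])
  clw7 <- ampliMHC:::.classLogLik(states, po, 1, pi, 2, om7,
    props = rep(0.1, 10))
  l7 <- ampliMHC:::.mixLogLik(clw7, rep(0.1, 10))
  p1 <- 1e-9
  om8 <- c(om7, 5)
  pr8 <- c(rep((1 - p1) / 10, 10), p1)
  clw8 <- ampliMHC:::.classLogLik(states, po, 1, pi, 2, om8, props = pr8)
  l8 <- ampliMHC:::.mixLogLik(clw8, pr8)
  expect_lt(abs(l7 - l8), 0.01)
})

test_that("LRT bookkeeping: nesting, df, degenerate equality", {
  set.seed(13)
  tr <- ape::rcoal(6)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 2
  sim <- simulateCodonAlignment(tr, 30, omegas = 0.5, seed = 14)
  f0 <- fitSiteModel(sim$aln, tr, "M0", nstarts = 1)
  expect_equal(f0@npar, 1L)
  lrt0 <- likelihoodRatioTest(f0, f0)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p, 1)
  f1 <- fitSiteModel(sim$aln, tr, "M1a", scale = f0@params$scale,
    nstarts = 1)
  f2 <- fitSiteModel(sim$aln, tr, "M2a", scale = f0@params$scale,
    nstarts = 1)
  lrt <- likelihoodRatioTest(f1, f2, tol = 2)
  expect_equal(lrt$df, 2L)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
  expect_error(likelihoodRatioTest(f0, f2), "nested")
  expect_error(bebSitePosteriors(f0, sim$aln, tr), "unsupported")
  expect_equal(sum(f2@classProp), 1, tolerance = 1e-9)
})

test_that("BEB finds no positive sites in data without selection signal", {
  set.seed(17)
  tr <- ape::rcoal(8)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 4
  sim <- simulateCodonAlignment(tr, 40, omegas = 0.2, seed = 18)
  f2 <- fitSiteModel(sim$aln, tr, "M2a", optimize_scale = TRUE, nstarts = 1)
  beb <- bebSitePosteriors(f2, sim$aln, tr)
  expect_length(beb$pss95, 0)
  expect_true(all(beb$sites$p_positive >= 0 & beb$sites$p_positive <= 1))
})
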