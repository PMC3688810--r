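test_that("single-codon cases match hand calculation", {
  same <- ng86Pairwise("TTTAAA", "TTTAAA")
  expect_equal(unname(same[c("Nd", "Sd", "dN", "dS")]), c(0, 0, 0, 0))
  # TTT (Phe) -> TTA (Leu): one nonsynonymous difference
  one <- ng86Pairwise("TTT", "TTA")
  expect_equal(unname(one["Nd"]), 1)
  expect_equal(unname(one["Sd"]), 0)
  # TTT -> TTC: synonymous third-position change (raw counts; a single
  # fully synonymous codon saturates the JC correction by construction)
  syn <- ng86Pairwise("TTT", "TTC", jc = FALSE)
  expect_equal(unname(syn["Sd"]), 1)
  expect_equal(unname(syn["Nd"]), 0)
})

test_that("pairwise NG86 equals the exhaustive-pathway oracle", {
  # all codon pairs differ by <= 3 positions: complete enumeration
  sense <- senseCodons()
  set.seed(7)
  pick <- sample(length(sense), 25)
  for (i in pick) {
    for (j in sample(length(sense), 8)) {
      got <- ng86Pairwise(sense[i], sense[j], jc = FALSE)
      want <- oracle_ng86(sense[i], sense[j])
      expect_equal(unname(got[c("N", "S", "Nd", "Sd")]), want,
        tolerance = 1e-12)
    }
  }
  # random 30-codon pairs
  for (s in 1:5) {
    a <- random_codon_seq(30, seed = s)
    b <- ampliMHC:::.mutateCoding(a, 0.08)
    got <- ng86Pairwise(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(unname(got[c("N", "S", "Nd", "Sd")]), want,
      tolerance = 1e-9)
  }
})

test_that("partition rates: zeros on identical sequences, ABS subsetting", {
  seqs <- c(a = random_codon_seq(30, 1), b = random_codon_seq(30, 1),
    c = random_codon_seq(30, 1))
  aln <- codonAlignment(seqs, abs_mask = 1:10)
  res <- partitionRates(aln, "all", bootstrap_reps = 100)
  expect_equal(c(res$dN, res$dS), c(0, 0))
  expect_equal(res$Z, 0)
  expect_equal(res$p, 1)
  pool <- generateAllelePool(6, seed = 4)
  aln2 <- codonAlignment(alleleSequences(pool), abs_mask = 1:20)
  rall <- partitionRates(aln2, "all", bootstrap_reps = 200, seed = 2)
  rabs <- partitionRates(aln2, "ABS", bootstrap_reps = 200, seed = 2)
  expect_equal(rabs$n_codons, 20)
  expect_equal(rall$n_codons, 92)
  expect_true(rall$dN >= 0 && rall$dS >= 0)
  expect_warning(partitionRates(aln2, 1:2, bootstrap_reps = 100),
    "smaller than 3")
})

test_that("Z-test conventions and neutral-simulation coverage", {
  # dN = dS (identical) -> p = 1; negative Z reported as p = 1
  fake <- list(dN = 0.1, dS = 0.2, SE_diff = 0.05)
  z <- zTestSelection(fake)
  expect_lt(z[["Z"]], 0)
  expect_equal(z[["p"]], 1)
  degen <- zTestSelection(list(dN = 0.1, dS = 0.1, SE_diff = 0))
  expect_equal(as.numeric(degen), c(0, 1))
  expect_true(isTRUE(attr(degen, "degenerate")))
  # neutral codon simulation: dN within 2 SE of dS
  tr <- ape::rcoal(8)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 3
  sim <- simulateCodonAlignment(tr, 60, omegas = 1, seed = 11)
  res <- partitionRates(sim$aln, "all", bootstrap_reps = 300, seed = 1)
  expect_lt(abs(res$dN - res$dS), 2 * res$SE_diff + 0.05)
})
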