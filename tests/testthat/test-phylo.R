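test_that("distances: p and Jukes-Cantor forms, saturation handling", {
  s <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  expect_equal(alignmentDistances(s)["a", "b"], 0)
  # p = 0.05 -> d ~ 0.0517
  b <- s[["a"]]
  for (p in seq(1, 97, by = 20)) substr(b, p, p) <- "T"
  s2 <- c(a = s[["a"]], b = b)
  pd <- alignmentDistances(s2, "p")["a", "b"]
  expect_equal(alignmentDistances(s2, "JC")["a", "b"],
    -0.75 * log(1 - 4 / 3 * pd))
  expect_equal(round(-0.75 * log(1 - 4 / 3 * 0.05), 4), 0.0517)
  # JC >= p for all unsaturated pairs
  set.seed(2)
  pool <- generateAllelePool(6, seed = 2)
  pp <- alignmentDistances(alleleSequences(pool), "p")
  jc <- alignmentDistances(alleleSequences(pool), "JC")
  off <- upper.tri(pp)
  expect_true(all(jc[off] >= pp[off]))
  sat <- c(a = strrep("A", 20), b = strrep("C", 20), c = strrep("G", 20))
  expect_error(alignmentDistances(sat, "JC"), "saturation")
})

test_that("NJ recovers additive trees exactly", {
  expect_error(njTree(matrix(0, 2, 2)), "size")
  # additive 4-taxon matrix from a known tree
  tr0 <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.05);")
  dm <- ape::cophenetic.phylo(tr0)
  tr <- njTree(dm)
  expect_equal(sort(tr$tip.label), c("a", "b", "c", "d"))
  back <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_true(all(abs(back - dm) < 1e-9))
  expect_identical(ape::dist.topo(ape::unroot(tr0), tr)[1], 0)
  # 3 taxa: branch lengths solve the three-point formulas
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
    dimnames = list(letters[1:3], letters[1:3]))
  t3 <- njTree(d3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(el["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(el["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(el["c"]), (4 + 5 - 3) / 2)
})

test_that("two simulated lineages form monophyletic clusters with support", {
  pool <- generateAllelePool(7, seed = 12)
  seqs <- alleleSequences(pool)
  lin <- alleleLineages(pool)
  tr <- bootstrapSupport(seqs, replicates = 100, seed = 3)
  expect_true(ape::is.monophyletic(tr, names(lin)[lin == "DAB1"]))
  expect_true(ape::is.monophyletic(tr, names(lin)[lin == "DAB3"]))
  sup <- attr(tr, "support")
  expect_true(all(sup >= 0 & sup <= 100))
  # the deep lineage split is near-unanimously supported
  split_node <- ape::getMRCA(tr, names(lin)[lin == "DAB1"])
  expect_gte(sup[split_node - length(tr$tip.label)], 95)
  # determinism under fixed seed
  tr2 <- bootstrapSupport(seqs, replicates = 100, seed = 3)
  expect_identical(attr(tr, "support"), attr(tr2, "support"))
  # single replicate: supports are 0 or 100
  tr1 <- bootstrapSupport(seqs, replicates = 1, seed = 4, min_support = 0)
  expect_true(all(attr(tr1, "support") %in% c(0, 100)))
})
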