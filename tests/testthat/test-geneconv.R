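test_that("fragment search degenerates correctly", {
  same <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  expect_warning(hits <- findInnerFragments(same), "no polymorphic")
  expect_equal(nrow(hits), 0)
  expect_error(findInnerFragments(same[1:2]), ">= 3")
})

test_that("fragment boundaries land on polymorphic columns", {
  pool <- generateAllelePool(5, divergence = 0.05, seed = 31)
  seqs <- alleleSequences(pool)[1:5]
  smat <- do.call(rbind, strsplit(unname(seqs), ""))
  poly <- which(apply(smat, 2, function(x) length(unique(x)) > 1))
  hits <- findInnerFragments(seqs)
  expect_true(all(hits$start %in% poly))
  expect_true(all(hits$end %in% poly))
  expect_true(all(hits$start <= hits$end))
  # invariance to sequence input order (same fragment set)
  hits2 <- findInnerFragments(rev(seqs))
  key <- function(h) sort(paste(pmin(h$seq1, h$seq2), pmax(h$seq1, h$seq2),
    h$start, h$end))
  expect_identical(key(hits), key(hits2))
})

test_that("a constructed recombinant yields a significant inner fragment", {
  pool <- generateAllelePool(6, divergence = 0.05, seed = 11)
  seqs <- alleleSequences(pool)[1:6]
  A <- seqs[[1]]; B <- seqs[[2]]
  rec <- paste0(substr(A, 1, 138), substr(B, 139, 276))
  test_set <- c(seqs[3:6], A = A, B = B, REC = rec)
  res <- geneconvScan(test_set, n_perm = 1000, seed = 1)
  expect_lte(res$global_inner_p, 0.01)
  top <- res$inner[1, ]
  expect_true("REC" %in% c(top$seq1, top$seq2))
  # the top fragment spans (a large part of) the donated half
  expect_gt(top$end - top$start, 80)
  expect_true(all(res$inner$sim_p > 0 & res$inner$sim_p <= 1))
})

test_that("outer fragments flag a spliced-in external segment", {
  pool <- generateAllelePool(5, divergence = 0.01, seed = 41)
  seqs <- alleleSequences(pool)[1:5]
  foreign <- alleleSequences(pool)[[8]]   # other lineage = external source
  spliced <- paste0(substr(seqs[[1]], 1, 100), substr(foreign, 101, 200),
    substr(seqs[[1]], 201, 276))
  test_set <- c(seqs[2:5], SPL = spliced)
  res <- geneconvScan(test_set, n_perm = 500, seed = 2)
  # the spliced sequence carries the top-scoring outer fragment, inside
  # the donated region (run-length scores of a 20%-diverged donor are
  # short, so location, not significance, is the check here)
  top <- res$outer[1, ]
  expect_identical(top$seq, "SPL")
  expect_true(top$start >= 95 && top$end <= 205)
})

test_that("permutation p-values respect their bounds", {
  pool <- generateAllelePool(4, divergence = 0.05, seed = 21)
  seqs <- alleleSequences(pool)[1:4]
  res <- geneconvScan(seqs, n_perm = 100, seed = 3)
  expect_error(permutationSignificance(seqs, n_perm = 50), ">= 100")
  if (!is.null(res$inner) && nrow(res$inner)) {
    expect_true(all(res$inner$sim_p >= 1 / 101))
    expect_true(all(res$inner$bc_ka_p <= 1))
  }
})
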