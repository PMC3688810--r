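test_that("per-tag predicates reject homopolymers and tandem motifs", {
  cand <- enumerateCandidateTags(7, no_motif_repeat = FALSE)
  # no-adjacent-repeat words over a 4-letter alphabet: 4 * 3^(L-1)
  expect_equal(length(cand), 4 * 3^6)
  expect_false("AACGTGA" %in% cand)          # adjacent AA
  cand2 <- enumerateCandidateTags(7)
  expect_false("ACACGTG" %in% cand2)         # tandem "AC" motif
  expect_false(any(grepl("(AA|CC|GG|TT)", cand2)))
  expect_true(all(cand2 %in% cand))
  expect_identical(cand2, sort(cand2))
})

test_that("greedy tag selection reaches the target at min distance 3", {
  cand <- enumerateCandidateTags(7)
  ts <- selectTagSet(cand, min_hamming = 3, target_size = 40, seed = 1)
  expect_gte(length(ts), 40)
  d <- combn(length(ts), 2, function(ij)
    hammingDistance(ts[ij[1]], ts[ij[2]]))
  expect_true(all(d >= 3))
  # reproducible under fixed seed / candidate order
  expect_identical(ts, selectTagSet(cand, 3, 40, seed = 1))
  # target 1 is vacuously satisfiable (a superset remains valid)
  expect_gte(length(selectTagSet(cand, 3, target_size = 1)), 1)
  # infeasible target reports best size found
  expect_error(selectTagSet(cand[1:5], 7, target_size = 4, restarts = 1),
    "best set found")
})

test_that("plate layout assigns unique tag pairs and respects capacity", {
  ts <- selectTagSet(enumerateCandidateTags(7), 3, 40)
  lay <- buildPlateLayout(ts, 12, 8, sprintf("S%02d", 1:96))
  expect_equal(nrow(lay), 96)
  expect_equal(nrow(unique(lay[, c("forward_tag", "reverse_tag")])), 96)
  expect_equal(sum(!is.na(lay$specimen)), 96)
  one <- buildPlateLayout(ts, 1, 1, "X")
  expect_equal(nrow(one), 1)
  expect_error(buildPlateLayout(ts, 12, 8, sprintf("S%02d", 1:97)),
    "capacity")
})

test_that("plate layout round-trips through CSV losslessly", {
  ts <- selectTagSet(enumerateCandidateTags(7), 3, 40)
  lay <- buildPlateLayout(ts, 4, 3, sprintf("S%02d", 1:10))
  path <- tempfile(fileext = ".csv")
  writePlateLayout(lay, path)
  back <- readPlateLayout(path)
  expect_equal(back, lay)
})
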