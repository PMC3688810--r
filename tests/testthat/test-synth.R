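test_that("allele pools have the exon-2 frame and two separable lineages", {
  pool <- generateAllelePool(5, seed = 1)
  seqs <- alleleSequences(pool)
  expect_true(all(nchar(seqs) == 276))
  aa <- translateCodons(ampliMHC:::.toCodonMatrix(seqs))
  expect_false(any(aa == "*"))
  lin <- alleleLineages(pool)
  dm <- alignmentDistances(seqs, model = "p")
  within <- c(dm[lin == "DAB1", lin == "DAB1"], dm[lin == "DAB3", lin == "DAB3"])
  between <- dm[lin == "DAB1", lin == "DAB3"]
  expect_gt(min(between), max(within))
  # at least one shared allele per lineage when n >= 3
  expect_true(all(tapply(speciesAssignment(pool) == "shared", lin, any)))
  expect_error(generateAllelePool(3, exon2_length = 277), "frame")
})

test_that("pool generation is deterministic and handles degenerate sizes", {
  p1 <- generateAllelePool(10, seed = 42)
  p2 <- generateAllelePool(10, seed = 42)
  expect_identical(alleleSequences(p1), alleleSequences(p2))
  p0 <- generateAllelePool(1, divergence = 0, seed = 1)
  expect_length(p0, 2)
  expect_false(alleleSequences(p0)[1] == alleleSequences(p0)[2])
})

test_that("simulated genotypes respect the 8-allele / 4-per-lineage caps", {
  pool <- generateAllelePool(8, seed = 2)
  geno <- simulateGenotypes(pool, 1000, seed = 3)
  expect_true(all(geno$n_alleles <= 8))
  lin <- alleleLineages(pool)
  per_lin <- vapply(strsplit(geno$alleles, ","), function(a)
    max(table(factor(lin[a], levels = c("DAB1", "DAB3")))), numeric(1))
  expect_true(all(per_lin <= 4))
  # degenerate weights: exactly 1 DAB1 + 2 DAB3 alleles everywhere
  w <- list(A = list(DAB1 = c(`1` = 1), DAB3 = c(`2` = 1)))
  g3 <- simulateGenotypes(pool, 50, species_probs = c(A = 1),
    pattern_weights = w, seed = 4)
  expect_true(all(g3$n_alleles == 3))
  # DAB3-skewed species A: majority carry no DAB1 allele
  geno_a <- geno[geno$species == "A", ]
  n_dab1 <- vapply(strsplit(geno_a$alleles, ","), function(a)
    sum(lin[a] == "DAB1"), numeric(1))
  expect_gt(mean(n_dab1 == 0), 0.5)
  bad <- list(A = list(DAB1 = c(`1` = 0.5), DAB3 = c(`1` = 1)))
  expect_error(simulateGenotypes(pool, 5, species_probs = c(A = 1),
    pattern_weights = bad), "sum to 1")
})

test_that("read simulation matches its truth table", {
  fx <- fixture_cohort(n_per_lineage = 4, n_specimens = 6,
    coverage = c(50, 80), seed = 9)
  sim <- fx$sim
  # truth complete: every read exactly once
  expect_identical(sort(names(sim$reads)), sort(sim$truth$read))
  expect_false(anyDuplicated(sim$truth$read) > 0)
  # noiseless reads reconstruct exactly from their source templates
  pr <- dabPrimers()
  cfg <- markerConfig()
  seqs <- alleleSequences(fx$pool)
  pure <- sim$truth[!sim$truth$chimeric, ]
  idx <- sample(nrow(pure), 20)
  for (i in idx) {
    row <- pure[i, ]
    lrow <- fx$layout[!is.na(fx$layout$specimen) &
      fx$layout$specimen == row$specimen, ]
    p <- pr[pr$marker == row$marker, ]
    expected <- paste0(lrow$forward_tag, p$forward,
      cfg[[row$marker]]$flank5, seqs[[row$allele]], cfg[[row$marker]]$flank3,
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(p$reverse))),
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(lrow$reverse_tag))))
    expect_identical(unname(sim$reads[row$read]), expected)
  }
})

test_that("chimera fraction and point errors behave as configured", {
  fx <- fixture_cohort(n_per_lineage = 6, n_specimens = 10,
    coverage = c(300, 400), error_rate = 0.01, chimera_fraction = 0.05,
    seed = 21)
  tr <- fx$sim$truth
  # chimeric reads only occur in multi-allele amplicons; overall fraction
  # within 3 binomial SDs of 5% among eligible reads
  amp <- paste(tr$specimen, tr$marker)
  eligible <- ave(tr$chimeric, amp, FUN = function(x) TRUE)
  multi <- names(which(tapply(tr$allele, amp, function(a)
    length(unique(a[!is.na(a)])) > 1)))
  sub <- tr[amp %in% multi, ]
  phat <- mean(sub$chimeric)
  se <- sqrt(0.05 * 0.95 / nrow(sub))
  expect_lt(abs(phat - 0.05), 3 * se)
  # majority vote: the modal full-read sequence of an amplicon is an
  # error-free copy of a true template
  reads <- fx$sim$reads
  one_amp <- sub[sub$specimen == sub$specimen[1] &
    sub$marker == sub$marker[1], ]
  full_tab <- sort(table(reads[one_amp$read]), decreasing = TRUE)
  modal <- names(full_tab)[1]
  clean <- one_amp$read[one_amp$n_errors == 0 & !one_amp$chimeric]
  expect_true(modal %in% reads[clean])
})

test_that("microsatellite panel divergence and determinism", {
  p1 <- simulateMicrosatPanel(10, c(30, 30), F = 0.3, seed = 7)
  p2 <- simulateMicrosatPanel(10, c(30, 30), F = 0.3, seed = 7)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_error(simulateMicrosatPanel(0, c(10, 10)), "n_loci")
  ms <- microsatArray(p1$genotypes)
  expect_equal(dim(ms$geno), c(60, 10, 2))
  # panmixia: theta near zero at n=200, 25 loci
  p0 <- simulateMicrosatPanel(25, c(100, 100), F = 0, seed = 8)
  ms0 <- microsatArray(p0$genotypes)
  th <- fstMicrosat(ms0$geno, ms0$pop, bootstrap_reps = 50)$fst
  expect_lt(abs(th), 0.02)
})
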