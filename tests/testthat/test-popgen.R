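test_that("binary F_ST: degenerate cases and bootstrap CI", {
  pops <- rep(c("X", "Y"), each = 50)
  # fixed complementary bands -> exactly 1
  m_fix <- cbind(matrix(rep(c(1L, 0L), each = 50), 100, 4),
    matrix(rep(c(0L, 1L), each = 50), 100, 4))
  r <- fstBinary(m_fix, pops, bootstrap_reps = 200)
  expect_identical(r$fst, 1)
  expect_true(r$ci_lo <= r$fst && r$fst <= r$ci_hi)
  # same band frequencies in both populations -> near zero
  set.seed(4)
  m_eq <- matrix(rbinom(100 * 20, 1, rep(runif(20, 0.3, 0.7), each = 100)),
    100, 20)
  r0 <- fstBinary(m_eq, pops, bootstrap_reps = 200)
  expect_lt(abs(r0$fst), 0.02)
  expect_error(fstBinary(matrix(1L, 40, 3), rep(c("X", "Y"), each = 20),
    bootstrap_reps = 10), "monomorphic")
})

test_that("binary F_ST tracks simulated divergence", {
  # presence/absence loci simulated from Balding-Nichols band frequencies
  est <- vapply(1:8, function(s) {
    set.seed(s)
    F <- 0.2
    anc <- runif(40, 0.2, 0.8)
    f1 <- rbeta(40, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
    f2 <- rbeta(40, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
    m <- rbind(
      matrix(rbinom(50 * 40, 1, rep(f1, each = 50)), 50, 40),
      matrix(rbinom(50 * 40, 1, rep(f2, each = 50)), 50, 40))
    fstBinary(m, rep(c("A", "B"), each = 50), bootstrap_reps = 10)$fst
  }, numeric(1))
  expect_gt(mean(est), 0.10)
  expect_lt(mean(est), 0.30)
})

test_that("haplotype F_ST equals a direct H_T/H_S computation", {
  pops <- rep(c("X", "Y"), each = 30)
  m_eq <- rbind(matrix(rep(c(1L, 0L, 1L, 1L), each = 30), 30, 4),
    matrix(rep(c(1L, 0L, 1L, 1L), each = 30), 30, 4))
  expect_identical(fstHaplotype(m_eq, pops)$fst, 0)
  m_fix <- cbind(rep(c(1L, 0L), each = 30), rep(c(0L, 1L), each = 30))
  expect_identical(fstHaplotype(m_fix, pops)$fst, 1)
  # oracle: brute-force H computation on random carrier tables
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rbinom(60 * 8, 1, 0.4), 60, 8)
    m[, 1] <- 1L  # keep both pops observed
    got <- fstHaplotype(m, pops)$fst
    c1 <- colSums(m[1:30, ]); c2 <- colSums(m[31:60, ])
    f1 <- c1 / sum(c1); f2 <- c2 / sum(c2)
    hs <- ((1 - sum(f1^2)) + (1 - sum(f2^2))) / 2
    ht <- 1 - sum(((f1 + f2) / 2)^2)
    expect_equal(got, (ht - hs) / ht, tolerance = 1e-12)
  }
})

test_that("admixture: K=1 degenerate, seed reproducibility, q rows sum to 1", {
  panel <- simulateMicrosatPanel(10, c(20, 20), F = 0.5, seed = 51)
  ms <- microsatArray(panel$genotypes)
  r1 <- admixtureInfer(ms$geno, K = 1, reps = 50, burn_in = 10, seed = 1)
  expect_true(all(r1$Q == 1))
  r2 <- admixtureInfer(ms$geno, K = 2, reps = 150, burn_in = 50, seed = 2)
  r3 <- admixtureInfer(ms$geno, K = 2, reps = 150, burn_in = 50, seed = 2)
  expect_identical(r2$Q, r3$Q)
  expect_equal(unname(rowSums(r2$Q)), rep(1, 40), tolerance = 1e-9)
  expect_error(admixtureInfer(ms$geno, K = 2, reps = 10, burn_in = 20),
    "reps > burn_in")
})

test_that("dominant-data admixture separates diverged populations", {
  set.seed(6)
  f1 <- runif(30, 0.05, 0.3)
  f2 <- runif(30, 0.7, 0.95)
  X <- rbind(matrix(rbinom(25 * 30, 1, rep(f1, each = 25)), 25, 30),
    matrix(rbinom(25 * 30, 1, rep(f2, each = 25)), 25, 30))
  r <- admixtureInfer(X, K = 2, reps = 400, burn_in = 100, seed = 3,
    model = "dominant")
  cl <- apply(r$Q, 1, which.max)
  acc <- max(mean(cl == rep(c(1, 2), each = 25)),
    mean(cl == rep(c(2, 1), each = 25)))
  expect_gte(acc, 0.95)
})

test_that("Evanno Delta-K table and run alignment", {
  mk <- function(K, L) list(K = as.integer(K), lnPD = L)
  runs <- list(mk(1, -100), mk(1, -101), mk(2, -50), mk(2, -52),
    mk(3, -49), mk(3, -51), mk(4, -48.5), mk(4, -50))
  dk <- evannoDeltaK(runs)
  expect_equal(dk$K, 1:4)
  expect_true(is.na(dk$deltaK[1]) && is.na(dk$deltaK[4]))
  # interior peak at K=2: |(-50) - 2*(-51) + (-100.5)| / sd
  expect_equal(dk$deltaK[2],
    abs(-50 - 2 * (-51) + (-100.5)) / sd(c(-50, -52)))
  # flat mean lnPD with nonzero SD -> Delta-K 0
  flat <- list(mk(1, -10), mk(1, -12), mk(2, -10), mk(2, -12),
    mk(3, -10), mk(3, -12))
  expect_equal(evannoDeltaK(flat)$deltaK[2], 0)
  expect_error(evannoDeltaK(runs[1:4]), "consecutive")
  # label-switched replicate runs align back to the reference
  q1 <- cbind(c(0.9, 0.8, 0.1), c(0.1, 0.2, 0.9))
  q2 <- q1[, 2:1]
  al <- alignReplicateRuns(list(q1, q2))
  expect_equal(al$consensus, q1)
  expect_equal(alignReplicateRuns(list(q1))$consensus, q1)
  expect_error(alignReplicateRuns(list(q1, q1[1:2, ])), "share")
})

test_that("Mantel test: self-correlation is 1, null is calibrated", {
  set.seed(8)
  mm <- matrix(runif(36), 6, 6)
  mm <- mm + t(mm); diag(mm) <- 0
  dimnames(mm) <- list(letters[1:6], letters[1:6])
  self <- mantelTest(mm, mm, n_perm = 200)
  expect_equal(self$r, 1)
  # independent matrices: p roughly uniform (coarse check at 30 reps)
  ps <- vapply(1:30, function(s) {
    set.seed(100 + s)
    a <- matrix(runif(49), 7, 7); a <- a + t(a); diag(a) <- 0
    b <- matrix(runif(49), 7, 7); b <- b + t(b); diag(b) <- 0
    mantelTest(a, b, n_perm = 200, seed = s)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 7 / 30)
  expect_error(mantelTest(mm[1:2, 1:2], mm[1:2, 1:2]), "at least 3")
})

test_that("diversity table counts private alleles and rarefies richness", {
  m <- rbind(s1 = c(1, 1, 0), s2 = c(1, 0, 0), s3 = c(0, 1, 1),
    s4 = c(0, 0, 1))
  colnames(m) <- paste0("al", 1:3)
  pm <- new("PresenceMatrix", presence = m,
    population = c("P1", "P1", "P2", "P2"))
  div <- diversityAndCorrelation(pm)
  tb <- div$table
  expect_equal(tb$mhc_alleles[tb$population == "P1"], 2)
  expect_equal(tb$mhc_private[tb$population == "P1"], 1)  # al1 only in P1
  expect_equal(tb$mhc_per_specimen[tb$population == "P1"], 1.5)
  # rarefaction: monomorphic locus -> richness exactly 1, below-floor NA
  panel <- simulateMicrosatPanel(6, c(12, 4), F = 0.1, seed = 9)
  pm2 <- new("PresenceMatrix",
    presence = matrix(rep(c(1L, 0L, 1L, 1L), 16), 16, 4),
    population = panel$genotypes$pop[match(unique(panel$genotypes$ind),
      panel$genotypes$ind)])
  div2 <- diversityAndCorrelation(pm2, panel$genotypes,
    rarefaction_floor = 8)
  t2 <- div2$table
  expect_true(is.na(t2$msat_richness[t2$population == "P2"]))  # n=4 < floor
  expect_false(is.na(t2$msat_richness[t2$population == "P1"]))
})
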