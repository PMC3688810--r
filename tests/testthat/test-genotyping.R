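test_that("demultiplexing assigns reads by tag pair and flags failures", {
  fx <- fixture_cohort(n_per_lineage = 4, n_specimens = 6,
    coverage = c(40, 60), seed = 5)
  dm <- demultiplexReads(fx$sim$reads, fx$layout, allow_mismatch = 0)
  expect_equal(nrow(dm$assigned) + nrow(dm$unassigned),
    length(fx$sim$reads))
  # noiseless: every read correctly assigned to its specimen
  truth_spec <- setNames(fx$sim$truth$specimen, fx$sim$truth$read)
  expect_equal(nrow(dm$unassigned), 0)
  expect_identical(unname(truth_spec[dm$assigned$read]),
    dm$assigned$specimen)
  # a read with a corrupted forward tag goes to unassigned
  bad <- fx$sim$reads[1]
  substr(bad, 1, 3) <- "NNN"
  dm2 <- demultiplexReads(bad, fx$layout)
  expect_equal(dm2$unassigned$reason, "forward tag unmatched")
})

test_that("tag-mutated reads are dropped but intact reads all assigned", {
  fx <- fixture_cohort(n_per_lineage = 4, n_specimens = 8,
    coverage = c(60, 90), error_rate = 0.01, seed = 6)
  dm <- demultiplexReads(fx$sim$reads, fx$layout, allow_mismatch = 0)
  tr <- fx$sim$truth
  intact <- tr$read[!tr$tag_mutated]
  expect_true(all(intact %in% dm$assigned$read))
  truth_spec <- setNames(tr$specimen, tr$read)
  ok <- dm$assigned$read %in% intact
  expect_identical(unname(truth_spec[dm$assigned$read[ok]]),
    dm$assigned$specimen[ok])
})

test_that("marker assignment by reference identity", {
  pool <- generateAllelePool(4, seed = 8)
  refs <- markerReferences(pool)
  expect_identical(assignMarker(refs[["DAB1"]], refs), "DAB1")
  set.seed(1)
  rnd <- paste(sample(c("A", "C", "G", "T"), nchar(refs[["DAB1"]]),
    replace = TRUE), collapse = "")
  expect_identical(assignMarker(rnd, refs), "unassigned")
  # 1% point errors on a DAB3 template still map to DAB3
  cfg <- markerConfig()
  lin <- alleleLineages(pool)
  a3 <- names(lin)[lin == "DAB3"][2]
  tmpl <- paste0(cfg$DAB3$flank5, alleleSequences(pool)[[a3]],
    cfg$DAB3$flank3)
  ch <- strsplit(tmpl, "")[[1]]
  pos <- sample(length(ch), 3)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  expect_identical(assignMarker(paste(ch, collapse = ""), refs), "DAB3")
  expect_error(assignMarker("ACGT", character(0)), "configuration")
})

make_vt <- function(bins) tabulateVariants(bins)

test_that("variant tabulation computes per-amplicon frequencies and MPAF", {
  A <- strrep("ATGCTG", 2)
  B <- strrep("ATGCTG", 2)
  substr(B, 1, 1) <- "G"
  bins <- rbind(
    data.frame(read = "x", specimen = "S1", marker = "DAB1",
      core = c(rep(A, 10), rep(B, 90))),
    data.frame(read = "x", specimen = "S2", marker = "DAB1",
      core = c(rep(A, 40), rep(B, 160)))
  )
  vt <- make_vt(bins)
  v <- variantInfo(vt)
  expect_equal(nrow(v), 2)
  freqs <- sweep(variantCounts(vt), 2, colSums(variantCounts(vt)), "/")
  expect_true(all(abs(colSums(freqs) - 1) < 1e-12))
  # variant A: 10/100 and 40/200 -> MPAF 0.20
  expect_equal(v$mpaf[v$sequence == A], 0.20)
  expect_equal(v$n_amplicons[v$sequence == A], 2)
  # singleton candidate bookkeeping
  bins2 <- rbind(bins, data.frame(read = "x", specimen = "S3",
    marker = "DAB1", core = rep(paste0("TT", substr(A, 3, 12)), 5)))
  v2 <- variantInfo(make_vt(bins2))
  expect_equal(v2$n_amplicons[3], 1)
})

test_that("classification applies the ordered MPAF rules", {
  L <- 12
  A <- "ATGATGATGATG"   # parent 1
  C <- "CCGTACCCGTAC"   # parent 2, far from A
  X <- A; substr(X, 7, 7) <- "C"               # 1-bp substitution of A
  D <- paste0(substr(A, 1, 6), substr(C, 7, L)) # chimera A|C
  E <- substr(A, 1, 11)                         # 1-bp deletion
  bins <- data.frame(read = "x", specimen = "S1", marker = "DAB1",
    core = c(rep(A, 450), rep(C, 510), rep(X, 20), rep(D, 15), rep(E, 5)))
  vt <- classifyAndCall(make_vt(bins), exon2_length = L)
  v <- variantInfo(vt)
  st <- setNames(v$status, v$sequence)
  expect_identical(unname(st[A]), "true_allele")        # MPAF 0.45 >= 5%
  expect_identical(unname(st[C]), "true_allele")        # MPAF >= 50%
  expect_identical(unname(st[X]), "artefact_substitution")
  expect_identical(unname(st[D]), "artefact_chimera")
  expect_identical(unname(st[E]), "excluded_frameshift")
  # idempotent: reclassifying its own output changes no status
  vt2 <- classifyAndCall(vt, exon2_length = L)
  expect_identical(variantInfo(vt2)$status, v$status)
})

test_that("singleton policy keeps high-MPAF singletons only", {
  L <- 12
  A <- "ATGATGATGATG"
  S_hi <- "CCGTACCCGTAC"  # singleton at 30% of its only amplicon
  S_lo <- "GGGTTTAAACCC"  # singleton at 8%
  bins <- rbind(
    data.frame(read = "x", specimen = "S1", marker = "DAB1",
      core = c(rep(A, 62), rep(S_hi, 30), rep(S_lo, 8))),
    data.frame(read = "x", specimen = "S2", marker = "DAB1",
      core = rep(A, 50)))
  vt <- classifyAndCall(make_vt(bins), exon2_length = L)
  st <- setNames(variantInfo(vt)$status, variantInfo(vt)$sequence)
  expect_identical(unname(st[S_hi]), "true_allele")
  expect_identical(unname(st[S_lo]), "excluded_singleton")
})

test_that("nomenclature prefixes follow species occurrence", {
  calls <- data.frame(
    specimen = c("a1", "a2", "b1", "a1", "b1", "h1"),
    marker = c("DAB3", "DAB3", "DAB3", "DAB1", "DAB3", "DAB3"),
    variant_id = c("V1", "V1", "V2", "V3", "V4", "V5"),
    sequence = c("AAA", "AAA", "CCC", "GGG", "TTT", "ACG"),
    freq = 0.5, stringsAsFactors = FALSE)
  meta <- data.frame(specimen = c("a1", "a2", "b1", "h1"),
    species = c("A", "A", "B", "hybrid"),
    population = "p", stringsAsFactors = FALSE)
  cat_ <- assignNomenclature(calls, meta)
  tb <- catalogTable(cat_)
  pre <- setNames(sub("-.*", "", tb$name), tb$variant_id)
  expect_identical(unname(pre["V1"]), "Pato")   # species A only
  expect_identical(unname(pre["V2"]), "Chna")   # species B only
  expect_identical(unname(pre["V5"]), "Pctn")   # hybrids only
  expect_true(grepl("^Pato-DAB1\\*\\d+$", tb$name[tb$variant_id == "V3"]))
  expect_false(anyDuplicated(tb$name) > 0)
  # shared A+B allele
  calls2 <- rbind(calls, data.frame(specimen = "b1", marker = "DAB3",
    variant_id = "V1", sequence = "AAA", freq = 0.5))
  pre2 <- setNames(sub("-.*", "",
    catalogTable(assignNomenclature(calls2, meta))$name),
    catalogTable(assignNomenclature(calls2, meta))$variant_id)
  expect_identical(unname(pre2["V1"]), "Pctn")
})

test_that("presence matrix rows mirror per-specimen allele counts", {
  calls <- data.frame(specimen = c("s1", "s2", "s2"),
    marker = "DAB3", variant_id = c("V1", "V1", "V2"),
    sequence = c("AAA", "AAA", "CCC"), freq = 0.5)
  meta <- data.frame(specimen = c("s1", "s2", "s3"),
    species = c("A", "A", "B"), population = c("p1", "p1", "p2"))
  expect_warning(pm <- buildPresenceMatrix(calls, NULL, meta),
    "without validated alleles")
  expect_equal(unname(rowSums(presence(pm))), c(1, 2, 0))
  expect_true(all(presence(pm) %in% 0:1))
})

test_that("population summary counts totals, ranges and private alleles", {
  m <- rbind(s1 = c(1, 0, 0), s2 = c(1, 1, 0), s3 = c(0, 0, 1))
  colnames(m) <- c("al1", "al2", "al3")
  pm <- new("PresenceMatrix", presence = m,
    population = c("P1", "P1", "P2"))
  cat_ <- new("AlleleCatalog", table = data.frame(
    name = colnames(m), variant_id = colnames(m),
    sequence = c("AAA", "CCC", "GGG"),
    lineage = c("DAB1", "DAB3", "DAB3"), occurrence = "A",
    n_specimens = 1))
  sm <- summarizePopulation(pm, cat_)
  s1 <- sm$summary[sm$summary$group == "P1", ]
  expect_equal(s1$n_alleles, 2)
  expect_equal(s1$private, 2)
  expect_equal(c(s1$min, s1$max), c(1, 2))
  expect_equal(s1$mean, 1.5)
  s2 <- sm$summary[sm$summary$group == "P2", ]
  expect_equal(s2$private, 1)
  expect_equal(s2$dab3, 1)
})

test_that("noiseless end-to-end genotyping recovers every allele exactly", {
  fx <- fixture_cohort(n_per_lineage = 8, n_specimens = 12,
    coverage = c(100, 200), seed = 3)
  gt <- genotypeReads(fx$sim$reads, fx$layout, fx$refs, fx$meta)
  seqs <- alleleSequences(fx$pool)
  lin <- alleleLineages(fx$pool)
  miss <- 0; fp <- 0
  for (i in seq_len(nrow(fx$geno))) {
    sp <- fx$geno$specimen[i]
    als <- strsplit(fx$geno$alleles[i], ",")[[1]]
    for (mk in c("DAB1", "DAB3")) {
      truth_seqs <- unname(seqs[als[lin[als] == mk]])
      called <- gt$calls$sequence[gt$calls$specimen == sp &
        gt$calls$marker == mk]
      miss <- miss + sum(!truth_seqs %in% called)
      fp <- fp + sum(!called %in% truth_seqs)
    }
  }
  expect_equal(miss, 0)   # 100% recall
  expect_equal(fp, 0)     # zero false positives
  expect_true(all(rowSums(presence(gt$presence)) <= 8))
})
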