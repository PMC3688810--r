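# Synthetic-data generator: allele pools for two divergent DAB lineages,
# per-specimen genotypes, tagged pyrosequencing-style reads with point-error
# and chimera artefacts, and microsatellite panels. Every output carries a
# ground-truth table so the genotyping and population-genetic modules can be
# validated end to end.

# Conserved exon-1/exon-3 flanks per marker (arbitrary fixed sequences).
# Interior product length (between primers) is 303 bp for DAB1 and 312 bp
# for DAB3, i.e. the 276-bp exon-2 core plus these flanks, so that the
# untagged products are 342/350 bp and the tagged products 356/364 bp.
.MARKER_CFG <- list(
  DAB1 = list(flank5 = "GACTGACCTGGAGTC", flank3 = "CCAGGTTCAGAG"),
  DAB3 = list(flank5 = "TGACCAGGAACTGTCTCA", flank3 = "AGGTCAGTCCTGAACTGA")
)

markerConfig <- function() .MARKER_CFG

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random stop-free codon sequence of n codons
.randomCodonSeq <- function(ncodon) {
  sense <- senseCodons()
  paste0(sample(sense, ncodon, replace = TRUE), collapse = "")
}

# mutate a coding sequence at `rate` per base, retrying codons that would
# create stops; bounded retries
.mutateCoding <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  nmut <- rbinom(1, n, rate)
  if (nmut == 0) return(seq)
  pos <- sample.int(n, nmut)
  for (p in pos) {
    cod_i <- (p - 1) %/% 3
    for (try in 1:10) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      cand <- chars
      cand[p] <- alt
      codon <- paste0(cand[(cod_i * 3 + 1):(cod_i * 3 + 3)], collapse = "")
      if (translateCodons(codon) != "*") {
        chars <- cand
        break
      }
    }
  }
  paste0(chars, collapse = "")
}

#' Generate a two-lineage allele pool
#'
#' Simulates an exon-2 allele pool with two deeply divergent gene lineages
#' (DAB1-like and DAB3-like), mimicking duplicated MHC IIB loci. Each
#' lineage descends from its own founder sequence; founders are separated by
#' `between_divergence` substitutions per site, alleles within a lineage by
#' up to `divergence`. All sequences are stop-free in frame 0 and the two
#' lineages form separable clusters (minimum between-lineage distance
#' exceeds the maximum within-lineage distance; regenerated on the rare
#' failure, with a bounded number of retries).
#'
#' @param n_per_lineage number of alleles per lineage (>= 1).
#' @param exon2_length exon-2 core length in bp, divisible by 3
#'   (default 276, i.e. 92 codons).
#' @param divergence within-lineage per-base substitution rate from the
#'   lineage founder (default 0.03).
#' @param between_divergence per-base divergence between lineage founders
#'   (default 0.2).
#' @param species_frac probabilities of assigning an allele to species A
#'   only, species B only, or shared (default c(0.4, 0.3, 0.3)).
#' @param seed integer seed.
#' @return An [AllelePool-class] object.
#' @export
generateAllelePool <- function(n_per_lineage, exon2_length = 276,
                               divergence = 0.03, between_divergence = 0.2,
                               species_frac = c(A = 0.4, B = 0.3, shared = 0.3),
                               seed = 1) {
  if (exon2_length %% 3 != 0)
    stop("frame error: exon2_length must be divisible by 3")
  stopifnot(n_per_lineage >= 1)
  set.seed(seed)
  ncodon <- exon2_length / 3

  for (attempt in 1:20) {
    founder1 <- .randomCodonSeq(ncodon)
    founder3 <- .mutateCoding(founder1, between_divergence)
    make_lineage <- function(founder, prefix) {
      out <- character(0)
      guard <- 0
      while (length(out) < n_per_lineage) {
        s <- if (length(out) == 0 && divergence == 0) founder
        else .mutateCoding(founder, divergence)
        if (divergence == 0 || !(s %in% out)) out <- c(out, s)
        guard <- guard + 1
        if (guard > 50 * n_per_lineage)
          stop("generation error: could not produce distinct stop-free alleles")
      }
      names(out) <- sprintf("%s_%02d", prefix, seq_along(out))
      out
    }
    s1 <- make_lineage(founder1, "L1")
    s3 <- make_lineage(founder3, "L3")
    seqs <- c(s1, s3)
    lin <- c(rep("DAB1", n_per_lineage), rep("DAB3", n_per_lineage))
    # lineage separability check
    dm <- as.matrix(ape::dist.dna(ape::as.DNAbin(
      Biostrings::DNAStringSet(seqs)), model = "raw", pairwise.deletion = TRUE))
    within_max <- max(c(dm[lin == "DAB1", lin == "DAB1"],
      dm[lin == "DAB3", lin == "DAB3"]), 0)
    between_min <- min(dm[lin == "DAB1", lin == "DAB3"])
    if (n_per_lineage == 1 || between_min > within_max) {
      assign <- sample(names(species_frac), 2 * n_per_lineage,
        replace = TRUE, prob = species_frac)
      # guarantee at least one shared allele per lineage when n >= 3
      if (n_per_lineage >= 3) {
        for (l in c("DAB1", "DAB3")) {
          if (!any(assign[lin == l] == "shared"))
            assign[which(lin == l)[1]] <- "shared"
          if (!any(assign[lin == l] == "A"))
            assign[which(lin == l)[2]] <- "A"
          if (!any(assign[lin == l] == "B"))
            assign[which(lin == l)[3]] <- "B"
        }
      }
      names(lin) <- names(seqs)
      names(assign) <- names(seqs)
      return(new("AllelePool", sequences = seqs, lineage = lin,
        speciesAssignment = assign, exon2Length = as.integer(exon2_length)))
    }
  }
  stop("generation error: lineages failed to separate after bounded retries")
}

.default_pattern_weights <- function() {
  list(
    A = list(DAB1 = c(`0` = 0.70, `1` = 0.25, `2` = 0.05),
             DAB3 = c(`0` = 0.02, `1` = 0.40, `2` = 0.45, `3` = 0.13)),
    B = list(DAB1 = c(`0` = 0.15, `1` = 0.55, `2` = 0.30),
             DAB3 = c(`0` = 0.05, `1` = 0.25, `2` = 0.45, `3` = 0.25)),
    hybrid = list(DAB1 = c(`0` = 0.45, `1` = 0.40, `2` = 0.15),
                  DAB3 = c(`0` = 0.03, `1` = 0.35, `2` = 0.45, `3` = 0.17))
  )
}

#' Simulate per-specimen genotypes
#'
#' Draws, for each specimen, a number of alleles per lineage according to
#' species-specific expression-pattern weights, then samples allele
#' identities (without replacement) from the alleles available to that
#' species (its own plus shared alleles; hybrids draw from the full pool).
#' Genotypes respect the biological caps: at most 4 alleles per lineage
#' (two duplicated diploid loci) and at most 8 in total.
#'
#' @param pool an [AllelePool-class].
#' @param n_specimens number of specimens.
#' @param species_probs sampling probabilities for species labels A, B and
#'   hybrid (default c(0.45, 0.45, 0.10)).
#' @param pattern_weights nested list `species -> lineage -> named probs`
#'   over per-lineage allele counts ("0".."4"); weights must sum to 1.
#'   Defaults emulate a native species expressing mostly the DAB3 lineage,
#'   an invasive species expressing both, and intermediate hybrids.
#' @param n_populations_per_species populations to split each species into.
#' @param seed integer seed.
#' @return data.frame with columns `specimen`, `population`, `species`,
#'   `alleles` (comma-separated allele ids), `n_alleles`.
#' @export
simulateGenotypes <- function(pool, n_specimens,
                              species_probs = c(A = 0.45, B = 0.45, hybrid = 0.10),
                              pattern_weights = NULL,
                              n_populations_per_species = 2,
                              seed = 1) {
  set.seed(seed)
  if (is.null(pattern_weights)) pattern_weights <- .default_pattern_weights()
  for (sp in names(pattern_weights)) {
    for (l in names(pattern_weights[[sp]])) {
      w <- pattern_weights[[sp]][[l]]
      if (abs(sum(w) - 1) > 1e-8) stop("pattern weights must sum to 1")
    }
  }
  lin <- alleleLineages(pool)
  assign <- speciesAssignment(pool)
  avail <- list(
    A = names(lin)[assign %in% c("A", "shared")],
    B = names(lin)[assign %in% c("B", "shared")],
    hybrid = names(lin)
  )
  for (sp in names(species_probs)) {
    if (species_probs[[sp]] > 0) {
      need <- names(which(vapply(pattern_weights[[sp]], function(w)
        sum(w[names(w) != "0"]) > 0, logical(1))))
      for (l in need) {
        if (!any(lin[avail[[sp]]] == l))
          stop("configuration error: pool lacks lineage ", l,
            " required for species ", sp)
      }
    }
  }
  species <- sample(names(species_probs), n_specimens, replace = TRUE,
    prob = species_probs)
  out <- vector("list", n_specimens)
  for (i in seq_len(n_specimens)) {
    sp <- species[i]
    pw <- pattern_weights[[sp]]
    repeat {
      n1 <- as.integer(sample(names(pw$DAB1), 1, prob = pw$DAB1))
      n3 <- as.integer(sample(names(pw$DAB3), 1, prob = pw$DAB3))
      if (n1 + n3 >= 1) break
    }
    pick <- function(lineage, k) {
      cand <- avail[[sp]][lin[avail[[sp]]] == lineage]
      sample(cand, min(k, length(cand)))
    }
    als <- c(pick("DAB1", min(n1, 4L)), pick("DAB3", min(n3, 4L)))
    out[[i]] <- als
  }
  pop_idx <- (seq_len(n_specimens) %% n_populations_per_species) + 1
  data.frame(
    specimen = sprintf("S%03d", seq_len(n_specimens)),
    population = paste0(species, pop_idx),
    species = species,
    alleles = vapply(out, paste, character(1), collapse = ","),
    n_alleles = lengths(out),
    stringsAsFactors = FALSE
  )
}

#' Simulate a tagged amplicon read set with known truth
#'
#' Emits, per specimen and marker, a read pool of structure
#' `forward tag + forward primer + template + revcomp(reverse primer) +
#' revcomp(reverse tag)`, where the template is the exon-2 core of a
#' genotype allele padded by conserved exon-1/exon-3 flanks. Artefacts:
#' uniform point errors over the whole read (tags included) and chimeric
#' reads formed by a single uniform crossover between two distinct templates
#' of the same amplicon. All reads are emitted in forward orientation.
#'
#' @param genotypes data.frame from [simulateGenotypes()].
#' @param pool the [AllelePool-class] the genotypes were drawn from.
#' @param layout plate layout data.frame mapping each specimen to a
#'   (forward_tag, reverse_tag) pair, as from [buildPlateLayout()].
#' @param coverage integer pair: per-amplicon read count range
#'   (default c(300, 2000), hundreds to thousands).
#' @param error_rate per-base point error probability (default 0.005).
#' @param chimera_fraction fraction of reads that are chimeric
#'   (default 0.02; requires >= 2 alleles in the amplicon).
#' @param share_alpha if non-NULL, Dirichlet concentration for unequal
#'   within-amplicon allele shares; NULL = equal shares.
#' @param seed integer seed.
#' @return list with `reads` (named character vector of read sequences) and
#'   `truth` (data.frame: read id, specimen, marker, allele, chimeric flag,
#'   chimera parents and breakpoint, error count, tag_mutated flag).
#' @export
simulateReadSet <- function(genotypes, pool, layout,
                            coverage = c(300, 2000), error_rate = 0.005,
                            chimera_fraction = 0.02, share_alpha = NULL,
                            seed = 1) {
  stopifnot(coverage[1] >= 1, error_rate >= 0, error_rate <= 1,
    chimera_fraction >= 0, chimera_fraction < 1)
  set.seed(seed)
  primers <- dabPrimers()
  seqs <- alleleSequences(pool)
  lin <- alleleLineages(pool)
  reads <- character(0)
  truth <- list()
  rid <- 0L

  for (i in seq_len(nrow(genotypes))) {
    spec <- genotypes$specimen[i]
    row <- layout[!is.na(layout$specimen) & layout$specimen == spec, ]
    if (nrow(row) == 0)
      stop("layout error: specimen ", spec, " has no assigned tag pair")
    ftag <- row$forward_tag[1]
    rtag <- row$reverse_tag[1]
    als <- strsplit(genotypes$alleles[i], ",")[[1]]
    for (mk in c("DAB1", "DAB3")) {
      mk_als <- als[lin[als] == mk]
      if (!length(mk_als)) next
      pr <- primers[primers$marker == mk, ]
      cfg <- .MARKER_CFG[[mk]]
      templates <- paste0(cfg$flank5, seqs[mk_als], cfg$flank3)
      names(templates) <- mk_als
      ncov <- sample(coverage[1]:coverage[2], 1)
      shares <- if (is.null(share_alpha)) {
        rep(1 / length(mk_als), length(mk_als))
      } else {
        g <- stats::rgamma(length(mk_als), share_alpha)
        g / sum(g)
      }
      n_chim <- if (length(mk_als) >= 2) rbinom(1, ncov, chimera_fraction) else 0L
      n_norm <- ncov - n_chim
      src <- sample(mk_als, n_norm, replace = TRUE, prob = shares)
      tmpl_reads <- templates[src]
      chim_info <- NULL
      if (n_chim > 0) {
        p1 <- sample(mk_als, n_chim, replace = TRUE, prob = shares)
        p2 <- vapply(p1, function(a)
          sample(setdiff(mk_als, a), 1), character(1))
        L <- nchar(templates[1])
        bp <- sample.int(L - 1L, n_chim, replace = TRUE)
        chim_seq <- vapply(seq_len(n_chim), function(k) {
          paste0(substr(templates[p1[k]], 1, bp[k]),
            substr(templates[p2[k]], bp[k] + 1, L))
        }, character(1))
        tmpl_reads <- c(tmpl_reads, chim_seq)
        chim_info <- data.frame(parent1 = p1, parent2 = p2, breakpoint = bp,
          stringsAsFactors = FALSE)
      }
      full <- paste0(ftag, pr$forward, tmpl_reads,
        .revcomp(pr$reverse), .revcomp(rtag))
      nerr <- integer(length(full))
      tagmut <- logical(length(full))
      if (error_rate > 0) {
        L <- nchar(full[1])
        nerr <- rbinom(length(full), L, error_rate)
        idx <- which(nerr > 0)
        for (k in idx) {
          chars <- strsplit(full[k], "")[[1]]
          pos <- sample.int(L, nerr[k])
          for (p in pos) {
            chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
          }
          full[k] <- paste0(chars, collapse = "")
          tagmut[k] <- any(pos <= 7L | pos > L - 7L)
        }
      }
      ids <- sprintf("read%07d", rid + seq_along(full))
      rid <- rid + length(full)
      names(full) <- ids
      reads <- c(reads, full)
      truth[[length(truth) + 1L]] <- data.frame(
        read = ids,
        specimen = spec,
        marker = mk,
        allele = c(src, if (n_chim > 0) rep(NA_character_, n_chim)),
        chimeric = c(rep(FALSE, n_norm), rep(TRUE, n_chim)),
        parent1 = c(rep(NA_character_, n_norm),
          if (n_chim > 0) chim_info$parent1),
        parent2 = c(rep(NA_character_, n_norm),
          if (n_chim > 0) chim_info$parent2),
        breakpoint = c(rep(NA_integer_, n_norm),
          if (n_chim > 0) chim_info$breakpoint),
        n_errors = nerr,
        tag_mutated = tagmut,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

#' Write reads as FASTQ / alleles as FASTA
#'
#' FASTQ qualities are constant high ("I" = Q40): downstream validation uses
#' read counts, not base qualities.
#'
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @export
writeReadsFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
      strrep("I", nchar(reads[[i]]))), con)
  }
  invisible(path)
}

#' @rdname writeReadsFastq
#' @export
readReadsFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' @rdname writeReadsFastq
#' @param seqs named character vector of sequences.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Marker reference sequences for a pool
#'
#' Returns one interior-product reference per marker (flanks + the first
#' allele of each lineage), used for marker assignment of reads.
#'
#' @param pool an [AllelePool-class].
#' @return named character vector (names "DAB1", "DAB3").
#' @export
markerReferences <- function(pool) {
  seqs <- alleleSequences(pool)
  lin <- alleleLineages(pool)
  out <- vapply(c("DAB1", "DAB3"), function(mk) {
    cfg <- .MARKER_CFG[[mk]]
    a <- names(lin)[lin == mk][1]
    paste0(cfg$flank5, seqs[a], cfg$flank3)
  }, character(1))
  out
}

#' Simulate a diploid microsatellite panel
#'
#' Balding-Nichols style divergence: per-locus ancestral allele frequencies
#' are Dirichlet(1); each population's frequencies are drawn from
#' Dirichlet(p * (1-F)/F) so the expected Wright F_ST between populations
#' equals `F` (F = 0 returns the ancestral frequencies unchanged,
#' i.e. panmixia). Hybrid individuals draw each allele copy from population
#' 1 with probability given by their admixture proportion.
#'
#' @param n_loci number of loci (default 25).
#' @param n_per_pop integer vector of sample sizes for the two parental
#'   populations.
#' @param F divergence parameter in [0, 1).
#' @param n_hybrids number of admixed individuals (population "H").
#' @param hybrid_q admixture proportion (ancestry in population 1) for
#'   hybrids (default 0.5).
#' @param n_alleles_range range of allele counts per locus.
#' @param seed integer seed.
#' @return list with `genotypes` (data.frame: ind, pop, locus, a1, a2 in
#'   allele-size units), `freqs` (per pop, per locus), `admixture`
#'   (data.frame ind, q1), and the arguments used.
#' @export
simulateMicrosatPanel <- function(n_loci = 25, n_per_pop = c(100, 100),
                                  F = 0.2, n_hybrids = 0, hybrid_q = 0.5,
                                  n_alleles_range = c(4, 10), seed = 1) {
  if (n_loci < 1) stop("configuration error: n_loci must be >= 1")
  stopifnot(F >= 0, F < 1)
  set.seed(seed)
  loci <- sprintf("Loc%02d", seq_len(n_loci))
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), alpha)
    if (sum(g) == 0) g <- rep(1, length(alpha))
    g / sum(g)
  }
  anc <- lapply(seq_len(n_loci), function(l) {
    k <- sample(n_alleles_range[1]:n_alleles_range[2], 1)
    p <- rdirichlet1(rep(1, k))
    names(p) <- as.character(100 + 2 * seq_len(k))
    p
  })
  popfreq <- function() {
    lapply(anc, function(p) {
      if (F == 0) return(p)
      q <- rdirichlet1(p * (1 - F) / F)
      names(q) <- names(p)
      q
    })
  }
  f1 <- popfreq()
  f2 <- popfreq()
  draw_geno <- function(freqs) {
    vapply(freqs, function(p)
      as.integer(sample(names(p), 2, replace = TRUE, prob = p)),
      integer(2))
  }
  rows <- list()
  ind_id <- 0
  emit <- function(pop, freq_pair, q1) {
    ind_id <<- ind_id + 1
    id <- sprintf("I%04d", ind_id)
    g <- vapply(seq_len(n_loci), function(l) {
      src <- stats::rbinom(2, 1, q1)  # 1 = pop1 ancestry
      vapply(1:2, function(cc) {
        p <- if (src[cc] == 1) freq_pair[[1]][[l]] else freq_pair[[2]][[l]]
        as.integer(sample(names(p), 1, prob = p))
      }, integer(1))
    }, integer(2))
    rows[[length(rows) + 1L]] <<- data.frame(
      ind = id, pop = pop, locus = loci, a1 = g[1, ], a2 = g[2, ],
      stringsAsFactors = FALSE)
    data.frame(ind = id, q1 = q1, stringsAsFactors = FALSE)
  }
  adm <- list()
  for (k in seq_len(n_per_pop[1]))
    adm[[length(adm) + 1]] <- emit("P1", list(f1, f2), 1)
  for (k in seq_len(n_per_pop[2]))
    adm[[length(adm) + 1]] <- emit("P2", list(f1, f2), 0)
  if (n_hybrids > 0) {
    for (k in seq_len(n_hybrids))
      adm[[length(adm) + 1]] <- emit("H", list(f1, f2), hybrid_q)
  }
  list(
    genotypes = do.call(rbind, rows),
    freqs = list(P1 = f1, P2 = f2),
    admixture = do.call(rbind, adm),
    loci = loci, F = F
  )
}

#' Reshape long microsatellite genotypes to an individual x locus table
#'
#' @param genotypes long data.frame from [simulateMicrosatPanel()].
#' @return list with `geno` (3-d array ind x locus x 2 of integer allele
#'   sizes), `pop` (per-individual population labels).
#' @export
microsatArray <- function(genotypes) {
  inds <- unique(genotypes$ind)
  loci <- unique(genotypes$locus)
  arr <- array(NA_integer_, c(length(inds), length(loci), 2),
    dimnames = list(inds, loci, NULL))
  i <- match(genotypes$ind, inds)
  l <- match(genotypes$locus, loci)
  arr[cbind(i, l, 1L)] <- genotypes$a1
  arr[cbind(i, l, 2L)] <- genotypes$a2
  pop <- genotypes$pop[match(inds, genotypes$ind)]
  list(geno = arr, pop = setNames(pop, inds))
}
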