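# Shared fixtures: small allele pools, cohorts and an independent
# Nei-Gojobori oracle used to cross-check the package implementation.

fixture_cohort <- function(n_per_lineage = 8, n_specimens = 12,
                           coverage = c(100, 200), error_rate = 0,
                           chimera_fraction = 0, seed = 3) {
  pool <- generateAllelePool(n_per_lineage, seed = seed)
  geno <- simulateGenotypes(pool, n_specimens, seed = seed + 1)
  tags <- selectTagSet(enumerateCandidateTags(7), 3, 40)
  layout <- buildPlateLayout(tags, 12, 8, geno$specimen)
  sim <- simulateReadSet(geno, pool, layout, coverage = coverage,
    error_rate = error_rate, chimera_fraction = chimera_fraction,
    seed = seed + 2)
  list(pool = pool, geno = geno, layout = layout, sim = sim,
    refs = markerReferences(pool),
    meta = geno[, c("specimen", "population", "species")])
}

# Independent NG86 oracle: explicit enumeration of mutational pathways with
# its own translation and site counting (no shared code with the package
# internals beyond the genetic code table).
oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_codon_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(codon)
  s <- 0
  for (p in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == ch[p]) next
      mut <- ch
      mut[p] <- b
      maa <- oracle_translate(paste(mut, collapse = ""))
      if (maa != "*" && maa == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

oracle_codon_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  pos <- which(ch1 != ch2)
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  walk <- function(ord, skip_stops) {
    cur <- ch1
    sy <- ns <- 0
    for (p in ord) {
      nxt <- cur
      nxt[p] <- ch2[p]
      a1 <- oracle_translate(paste(cur, collapse = ""))
      a2 <- oracle_translate(paste(nxt, collapse = ""))
      if (skip_stops && a2 == "*") return(NULL)
      if (a1 != "*" && a1 == a2) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    c(sy, ns)
  }
  paths <- oracle_perms(pos)
  res <- Filter(Negate(is.null), lapply(paths, walk, skip_stops = TRUE))
  if (!length(res)) res <- lapply(paths, walk, skip_stops = FALSE)
  m <- do.call(rbind, res)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

oracle_ng86 <- function(seq1, seq2) {
  nc <- nchar(seq1) / 3
  cods1 <- substring(seq1, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cods2 <- substring(seq2, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  S <- N <- Sd <- Nd <- 0
  for (k in seq_len(nc)) {
    s1 <- oracle_codon_sites(cods1[k])
    s2 <- oracle_codon_sites(cods2[k])
    S <- S + (s1["S"] + s2["S"]) / 2
    N <- N + (s1["N"] + s2["N"]) / 2
    d <- oracle_codon_diffs(cods1[k], cods2[k])
    Sd <- Sd + d["Sd"]
    Nd <- Nd + d["Nd"]
  }
  unname(c(N = N, S = S, Nd = Nd, Sd = Sd))
}

random_codon_seq <- function(ncodon, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(senseCodons(), ncodon, replace = TRUE), collapse = "")
}
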