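# Population structure and diversity from binary MHC presence/absence
# (dominant loci) and codominant microsatellites: F_ST estimators with
# bootstrap CIs over loci, a Gibbs-sampler admixture model with Evanno's
# Delta-K and replicate-run alignment, Mantel/Spearman tests, and
# diversity summaries with rarefaction.

.pair_list <- function(pops) {
  u <- unique(pops)
  if (length(u) < 2) stop("need at least two populations")
  combn(u, 2, simplify = FALSE)
}

# Weir-Cockerham style variance components on band frequencies of one
# binary (dominant) locus across r populations; returns c(num, den) so
# multi-locus estimates are ratios of sums.
.theta_components_binary <- function(x, pop) {
  pops <- unique(pop)
  r <- length(pops)
  n <- vapply(pops, function(p) sum(pop == p), numeric(1))
  xb <- vapply(pops, function(p) mean(x[pop == p]), numeric(1))
  ntot <- sum(n)
  nbar <- ntot / r
  nc <- (ntot - sum(n^2) / ntot) / (r - 1)
  xbar <- sum(n * xb) / ntot
  msp <- sum(n * (xb - xbar)^2) / (r - 1)
  msg <- sum(n * xb * (1 - xb)) / sum(n - 1)
  c(num = msp - msg, den = msp + (nc - 1) * msg)
}

#' Pairwise F_ST from binary dominant data
#'
#' AMOVA-style variance-component estimator on band (presence) frequencies,
#' each allele column treated as one dominant locus; multi-locus F_ST is
#' the ratio of summed components. 95% CIs by bootstrapping loci.
#'
#' @param pm a [PresenceMatrix-class] or a 0/1 matrix.
#' @param pops population labels (taken from `pm` if a PresenceMatrix).
#' @param bootstrap_reps bootstrap replicates over loci (default 20000).
#' @param min_n smallest population size admitted to a pairwise estimate
#'   (default 9, i.e. N > 8).
#' @param seed integer seed.
#' @return data.frame with one row per population pair: `pop1`, `pop2`,
#'   `fst`, `ci_lo`, `ci_hi`, `n_loci`.
#' @export
fstBinary <- function(pm, pops = NULL, bootstrap_reps = 20000, min_n = 9,
                      seed = 1) {
  m <- if (is(pm, "PresenceMatrix")) presence(pm) else pm
  if (is.null(pops)) pops <- populations(pm)
  stopifnot(length(pops) == nrow(m))
  set.seed(seed)
  out <- list()
  for (pr in .pair_list(pops)) {
    sel <- pops %in% pr
    sub <- m[sel, , drop = FALSE]
    sp <- pops[sel]
    if (min(table(sp)) < min_n) next
    keep <- apply(sub, 2, function(x) length(unique(x)) > 1)
    sub <- sub[, keep, drop = FALSE]
    if (!ncol(sub)) stop("F_st undefined: matrix monomorphic for pair ",
      pr[1], "/", pr[2])
    comp <- t(apply(sub, 2, .theta_components_binary, pop = sp))
    fst <- sum(comp[, "num"]) / sum(comp[, "den"])
    boot <- vapply(seq_len(bootstrap_reps), function(r) {
      i <- sample.int(nrow(comp), nrow(comp), replace = TRUE)
      sum(comp[i, "num"]) / sum(comp[i, "den"])
    }, numeric(1))
    ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out[[length(out) + 1]] <- data.frame(pop1 = pr[1], pop2 = pr[2],
      fst = fst, ci_lo = ci[1], ci_hi = ci[2], n_loci = ncol(sub),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pairwise F_ST from allele (haplotype) frequencies
#'
#' Wright-style F_ST = (H_T - H_S)/H_T on per-population allele frequency
#' vectors built from carrier counts (the number of individuals carrying
#' each allele, normalized to a frequency vector). `ht_weighting` selects
#' whether the total-population frequencies average the population vectors
#' equally or weight them by carrier counts.
#'
#' @inheritParams fstBinary
#' @param ht_weighting "equal" (default) or "size".
#' @return data.frame with one row per population pair: `pop1`, `pop2`,
#'   `fst`, `hs`, `ht`.
#' @export
fstHaplotype <- function(pm, pops = NULL, ht_weighting = c("equal", "size"),
                         min_n = 2) {
  ht_weighting <- match.arg(ht_weighting)
  m <- if (is(pm, "PresenceMatrix")) presence(pm) else pm
  if (is.null(pops)) pops <- populations(pm)
  out <- list()
  for (pr in .pair_list(pops)) {
    if (min(sum(pops == pr[1]), sum(pops == pr[2])) < min_n) next
    cnt <- rbind(colSums(m[pops == pr[1], , drop = FALSE]),
      colSums(m[pops == pr[2], , drop = FALSE]))
    if (any(rowSums(cnt) == 0))
      stop("population with zero allele observations in pair ",
        pr[1], "/", pr[2])
    f <- sweep(cnt, 1, rowSums(cnt), "/")
    hs <- mean(1 - rowSums(f^2))
    fbar <- if (ht_weighting == "equal") colMeans(f)
      else colSums(cnt) / sum(cnt)
    ht <- 1 - sum(fbar^2)
    fst <- if (ht > 0) (ht - hs) / ht else 0
    out[[length(out) + 1]] <- data.frame(pop1 = pr[1], pop2 = pr[2],
      fst = fst, hs = hs, ht = ht, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pairwise Weir-Cockerham F_ST for codominant microsatellites
#'
#' Standard multiallelic Weir & Cockerham (1984) theta, summing variance
#' components over alleles and loci; 95% CIs by bootstrapping loci.
#'
#' @param geno 3-d array (individuals x loci x 2) of integer allele codes,
#'   as from [microsatArray()].
#' @param pops per-individual population labels.
#' @param bootstrap_reps bootstrap replicates over loci (default 1000).
#' @param min_n population-size floor for a pairwise estimate.
#' @param seed integer seed.
#' @return data.frame with `pop1`, `pop2`, `fst`, `ci_lo`, `ci_hi`.
#' @export
fstMicrosat <- function(geno, pops, bootstrap_reps = 1000, min_n = 9,
                        seed = 1) {
  set.seed(seed)
  nloc <- dim(geno)[2]
  comp_locus <- function(sel, sp, l) {
    a1 <- geno[sel, l, 1]
    a2 <- geno[sel, l, 2]
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2) return(c(0, 0))
    upops <- unique(sp)
    r <- length(upops)
    n <- vapply(upops, function(p) sum(sp == p), numeric(1))
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    num <- den <- 0
    for (al in alleles) {
      p_i <- vapply(upops, function(p) {
        s <- sp == p
        mean(c(a1[s], a2[s]) == al)
      }, numeric(1))
      h_i <- vapply(upops, function(p) {
        s <- sp == p
        mean((a1[s] == al) != (a2[s] == al))
      }, numeric(1))
      pbar <- sum(n * p_i) / (r * nbar)
      s2 <- sum(n * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
        hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
        (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
    c(num, den)
  }
  out <- list()
  for (pr in .pair_list(pops)) {
    sel <- pops %in% pr
    sp <- pops[sel]
    if (min(table(sp)) < min_n) next
    comp <- t(vapply(seq_len(nloc), function(l) comp_locus(sel, sp, l),
      numeric(2)))
    fst <- sum(comp[, 1]) / sum(comp[, 2])
    boot <- vapply(seq_len(bootstrap_reps), function(r) {
      i <- sample.int(nloc, nloc, replace = TRUE)
      sum(comp[i, 1]) / sum(comp[i, 2])
    }, numeric(1))
    ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out[[length(out) + 1]] <- data.frame(pop1 = pr[1], pop2 = pr[2],
      fst = fst, ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Bayesian admixture clustering (Gibbs sampler)
#'
#' Admixture model with independent allele frequencies: each allele copy
#' (codominant data) or band observation (dominant data) carries a latent
#' cluster of origin; individual ancestry vectors q and cluster allele
#' frequencies are updated by their Dirichlet/Beta conjugate full
#' conditionals. Returns the posterior-mean Q matrix and an estimate of
#' ln P(Data | K) (mean of the sweep log-likelihoods minus half their
#' variance) used by [evannoDeltaK()].
#'
#' @param data for `model = "codominant"` a 3-d array
#'   (individuals x loci x 2) of integer allele codes; for `"dominant"` a
#'   0/1 matrix (individuals x loci).
#' @param K number of clusters.
#' @param reps total Gibbs sweeps (default 2000; the study-scale setting of
#'   4e6 replications is available by configuration).
#' @param burn_in discarded sweeps (default reps/5).
#' @param seed integer seed.
#' @param model "codominant" or "dominant".
#' @return list with `Q` (individuals x K posterior means, rows sum to 1),
#'   `K`, `lnPD`, `lnL_trace`.
#' @export
admixtureInfer <- function(data, K, reps = 2000, burn_in = reps %/% 5,
                           seed = 1, model = c("codominant", "dominant")) {
  model <- match.arg(model)
  stopifnot(K >= 1, reps > burn_in)
  set.seed(seed)
  rdir <- function(alpha) {
    g <- rgamma(length(alpha), alpha)
    g / sum(g)
  }
  if (model == "codominant") {
    nind <- dim(data)[1]
    nloc <- dim(data)[2]
    acode <- lapply(seq_len(nloc), function(l) {
      sort(unique(c(data[, l, 1], data[, l, 2])))
    })
    obs <- lapply(seq_len(nloc), function(l) {
      cbind(match(data[, l, 1], acode[[l]]), match(data[, l, 2], acode[[l]]))
    })
    ncop <- 2 * nloc
  } else {
    nind <- nrow(data)
    nloc <- ncol(data)
    ncop <- nloc
  }
  if (K == 1) {
    lnl <- if (model == "codominant") {
      sum(vapply(seq_len(nloc), function(l) {
        f <- tabulate(c(obs[[l]]), length(acode[[l]])) / (2 * nind)
        sum(log(f[c(obs[[l]])]))
      }, numeric(1)))
    } else {
      sum(vapply(seq_len(nloc), function(l) {
        f <- mean(data[, l])
        sum(log(ifelse(data[, l] == 1, max(f, 1e-12),
          max(1 - f, 1e-12))))
      }, numeric(1)))
    }
    return(list(Q = matrix(1, nind, 1), K = 1L, lnPD = lnl,
      lnL_trace = rep(lnl, 2)))
  }

  q <- matrix(1 / K, nind, K)
  if (model == "codominant") {
    p <- lapply(seq_len(nloc), function(l)
      matrix(1 / length(acode[[l]]), K, length(acode[[l]])))
  } else {
    p <- matrix(runif(K * nloc, 0.2, 0.8), K, nloc)
  }
  Qsum <- matrix(0, nind, K)
  nkeep <- 0
  lnl_trace <- numeric(0)
  for (sweep_i in seq_len(reps)) {
    zcounts <- matrix(0, nind, K)
    lnl <- 0
    if (model == "codominant") {
      for (l in seq_len(nloc)) {
        ol <- obs[[l]]
        pk <- p[[l]]
        acounts <- matrix(0, K, ncol(pk))
        for (cc in 1:2) {
          lik <- q * t(pk[, ol[, cc], drop = FALSE])  # nind x K
          rs <- rowSums(lik)
          lnl <- lnl + sum(log(pmax(rs, 1e-300)))
          u <- runif(nind) * rs
          cum <- t(apply(lik, 1, cumsum))
          z <- max.col(cum >= u, ties.method = "first")
          zcounts[cbind(seq_len(nind), z)] <-
            zcounts[cbind(seq_len(nind), z)] + 1
          for (k in seq_len(K)) {
            sel <- z == k
            if (any(sel))
              acounts[k, ] <- acounts[k, ] +
                tabulate(ol[sel, cc], ncol(pk))
          }
        }
        p[[l]] <- t(apply(acounts + 1, 1, rdir))
      }
    } else {
      for (l in seq_len(nloc)) {
        x <- data[, l]
        fk <- p[, l]
        lik <- q * vapply(fk, function(f)
          ifelse(x == 1, f, 1 - f), numeric(nind))
        rs <- rowSums(lik)
        lnl <- lnl + sum(log(pmax(rs, 1e-300)))
        u <- runif(nind) * rs
        cum <- t(apply(lik, 1, cumsum))
        z <- max.col(cum >= u, ties.method = "first")
        zcounts[cbind(seq_len(nind), z)] <-
          zcounts[cbind(seq_len(nind), z)] + 1
        for (k in seq_len(K)) {
          n1 <- sum(x == 1 & z == k)
          n0 <- sum(x == 0 & z == k)
          p[k, l] <- rbeta(1, 1 + n1, 1 + n0)
        }
      }
    }
    q <- t(apply(zcounts + 1, 1, rdir))
    if (sweep_i > burn_in) {
      # posterior mean of ancestry proportions from assignment counts
      Qsum <- Qsum + (zcounts + 1) / (ncop + K)
      nkeep <- nkeep + 1
      lnl_trace <- c(lnl_trace, lnl)
    }
  }
  Q <- Qsum / nkeep
  Q <- Q / rowSums(Q)
  lnPD <- mean(lnl_trace) - stats::var(lnl_trace) / 2
  list(Q = Q, K = as.integer(K), lnPD = lnPD, lnL_trace = lnl_trace)
}

#' Evanno's Delta-K from replicate admixture runs
#'
#' Delta-K(K) = mean |L(K+1) - 2 L(K) + L(K-1)| / SD[L(K)], defined for
#' interior K over at least three consecutive K values with >= 2 runs each.
#'
#' @param runs list of results from [admixtureInfer()] across K values and
#'   replicate runs.
#' @return data.frame with `K`, `mean_lnPD`, `sd_lnPD`, `deltaK` (NA at the
#'   boundary K; `Inf` with a warning where the SD is zero).
#' @export
evannoDeltaK <- function(runs) {
  K <- vapply(runs, function(r) r$K, integer(1))
  L <- vapply(runs, function(r) r$lnPD, numeric(1))
  ks <- sort(unique(K))
  if (length(ks) < 3 || any(diff(ks) != 1))
    stop("need >= 3 consecutive K values")
  if (any(table(K) < 2)) stop("need >= 2 runs per K")
  mu <- vapply(ks, function(k) mean(L[K == k]), numeric(1))
  sdv <- vapply(ks, function(k) sd(L[K == k]), numeric(1))
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    num <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1])
    if (sdv[i] == 0) {
      warning("zero SD of lnPD at K = ", ks[i], "; Delta-K infinite")
      dk[i] <- Inf
    } else {
      dk[i] <- num / sdv[i]
    }
  }
  data.frame(K = ks, mean_lnPD = mu, sd_lnPD = sdv, deltaK = dk)
}

#' Align replicate admixture runs (label switching)
#'
#' Greedy permutation of cluster labels per run maximizing the sum of
#' elementwise products with the first run's Q matrix; the consensus is the
#' mean of the aligned matrices.
#'
#' @param qmatrices list of Q matrices sharing dimensions.
#' @return list with `consensus` (Q matrix) and `permutations`.
#' @export
alignReplicateRuns <- function(qmatrices) {
  stopifnot(length(qmatrices) >= 1)
  dims <- vapply(qmatrices, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("runs must share K and individuals")
  K <- ncol(qmatrices[[1]])
  ref <- qmatrices[[1]]
  perms <- .permutations(seq_len(K))
  aligned <- list(ref)
  used_perms <- list(seq_len(K))
  for (r in seq_along(qmatrices)[-1]) {
    qr <- qmatrices[[r]]
    scores <- apply(perms, 1, function(pp) sum(ref * qr[, pp, drop = FALSE]))
    best <- perms[which.max(scores), ]
    aligned[[r]] <- qr[, best, drop = FALSE]
    used_perms[[r]] <- best
  }
  consensus <- Reduce(`+`, aligned) / length(aligned)
  list(consensus = consensus, permutations = used_perms)
}

#' Mantel test between two distance matrices
#'
#' Spearman (default) Mantel correlation of the off-diagonal distances with
#' significance by row/column permutation (delegated to
#' [vegan::mantel()]).
#'
#' @param m1,m2 symmetric matrices with matching dimnames, zero diagonal.
#' @param n_perm number of permutations (default 10000).
#' @param method correlation method (default "spearman").
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantelTest <- function(m1, m2, n_perm = 10000, method = "spearman",
                       seed = 1) {
  if (nrow(m1) < 3) stop("need at least 3 populations")
  stopifnot(all(dim(m1) == dim(m2)))
  if (!is.null(dimnames(m1)) && !is.null(dimnames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrix labels disagree")
  if (any(abs(m1 - t(m1)) > 1e-12) || any(abs(m2 - t(m2)) > 1e-12))
    stop("matrices must be symmetric")
  set.seed(seed)
  mt <- vegan::mantel(as.dist(m1), as.dist(m2), method = method,
    permutations = n_perm)
  list(r = unname(mt$statistic), p = mt$signif)
}

#' Pairwise F_ST table to symmetric matrix
#'
#' @param fst_df data.frame from one of the F_ST functions.
#' @return symmetric matrix with zero diagonal.
#' @export
fstMatrix <- function(fst_df) {
  pops <- sort(unique(c(fst_df$pop1, fst_df$pop2)))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(nrow(fst_df))) {
    m[fst_df$pop1[i], fst_df$pop2[i]] <- fst_df$fst[i]
    m[fst_df$pop2[i], fst_df$pop1[i]] <- fst_df$fst[i]
  }
  m
}

# expected number of distinct alleles in a subsample of g genes
.rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) return(NA_real_)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Per-population diversity and cross-marker correlation
#'
#' Summarizes, per population: MHC presence/absence diversity (number of
#' alleles, private alleles, mean alleles per specimen) and, when
#' microsatellite genotypes are supplied, the mean number of alleles per
#' locus, private alleles, and allelic richness rarefied to the smallest
#' population at or above the floor (populations below the floor are
#' reported as NA, i.e. "not evaluated"). The Spearman correlation between
#' microsatellite allelic richness and mean MHC alleles per specimen is
#' attached when both marker systems are present.
#'
#' @param pm a [PresenceMatrix-class].
#' @param msat optional long genotype data.frame from
#'   [simulateMicrosatPanel()] (with matching population labels in `pop`).
#' @param rarefaction_floor smallest population size (individuals) entering
#'   rarefaction (default 8).
#' @return list with `table` (per-population data.frame) and, if both
#'   markers present, `spearman` (list r, p).
#' @export
diversityAndCorrelation <- function(pm, msat = NULL, rarefaction_floor = 8) {
  m <- presence(pm)
  pops <- populations(pm)
  upop <- unique(pops)
  pres_by_pop <- sapply(upop, function(g)
    colSums(m[pops == g, , drop = FALSE]) > 0)
  tab <- data.frame(population = upop,
    n = vapply(upop, function(g) sum(pops == g), numeric(1)))
  tab$mhc_alleles <- colSums(pres_by_pop)
  tab$mhc_private <- vapply(upop, function(g)
    sum(pres_by_pop[, g] &
      rowSums(pres_by_pop[, upop != g, drop = FALSE]) == 0), numeric(1))
  tab$mhc_per_specimen <- vapply(upop, function(g)
    mean(rowSums(m[pops == g, , drop = FALSE])), numeric(1))

  if (!is.null(msat)) {
    loci <- unique(msat$locus)
    sizes <- vapply(upop, function(g)
      length(unique(msat$ind[msat$pop == g])), numeric(1))
    elig <- sizes >= rarefaction_floor
    gmin <- if (any(elig)) 2 * min(sizes[elig]) else NA
    allele_by_pop <- lapply(upop, function(g) {
      sub <- msat[msat$pop == g, ]
      lapply(loci, function(l)
        table(c(sub$a1[sub$locus == l], sub$a2[sub$locus == l])))
    })
    names(allele_by_pop) <- upop
    tab$msat_na <- vapply(upop, function(g)
      mean(lengths(allele_by_pop[[g]])), numeric(1))
    tab$msat_private <- vapply(upop, function(g) {
      others <- upop[upop != g]
      sum(vapply(seq_along(loci), function(li) {
        mine <- names(allele_by_pop[[g]][[li]])
        theirs <- unique(unlist(lapply(others, function(o)
          names(allele_by_pop[[o]][[li]]))))
        sum(!mine %in% theirs)
      }, numeric(1)))
    }, numeric(1))
    tab$msat_richness <- vapply(upop, function(g) {
      if (!elig[match(g, upop)] || is.na(gmin)) return(NA_real_)
      mean(vapply(allele_by_pop[[g]], function(ct)
        .rarefied_richness(as.numeric(ct), gmin), numeric(1)))
    }, numeric(1))
  }
  res <- list(table = tab)
  if (!is.null(msat)) {
    ok <- !is.na(tab$msat_richness)
    if (sum(ok) >= 3) {
      ct <- suppressWarnings(stats::cor.test(tab$msat_richness[ok],
        tab$mhc_per_specimen[ok], method = "spearman"))
      res$spearman <- list(r = unname(ct$estimate), p = ct$p.value)
    }
  }
  res
}
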