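# Nei-Gojobori (1986) synonymous / nonsynonymous substitution rates with
# Jukes-Cantor multiple-hit correction, partitioned over ABS / non-ABS
# codons, with codon-bootstrap standard errors and a one-tailed Z-test of
# positive selection (dN > dS).
#
# Conventions: potential sites per codon position are the fraction of the
# three possible changes that are synonymous (changes to stop codons count
# as nonsynonymous); observed differences in multi-hit codons are averaged
# over all minimal mutational pathways that avoid stop codons (if every
# pathway passes through a stop, all pathways are used).

.ng_site_env <- new.env(parent = emptyenv())

# per-codon (syn sites, nonsyn sites)
.codonSites <- function(codon) {
  if (is.null(.ng_site_env$tab)) .ng_site_env$tab <- list()
  hit <- .ng_site_env$tab[[codon]]
  if (!is.null(hit)) return(hit)
  chars <- strsplit(codon, "")[[1]]
  aa <- translateCodons(codon)
  syn <- 0
  for (p in 1:3) {
    for (alt in setdiff(c("T", "C", "A", "G"), chars[p])) {
      mut <- chars
      mut[p] <- alt
      maa <- translateCodons(paste0(mut, collapse = ""))
      if (maa != "*" && maa == aa) syn <- syn + 1 / 3
    }
  }
  res <- c(S = syn, N = 3 - syn)
  .ng_site_env$tab[[codon]] <- res
  res
}

# average (syn, nonsyn) differences between two codons over minimal
# stop-free pathways
.codonDiffs <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  pos <- which(ch1 != ch2)
  paths <- if (length(pos) == 1) list(pos) else
    lapply(asplit(.permutations(pos), 1), as.integer)
  count_path <- function(ord) {
    cur <- ch1
    s <- 0
    n <- 0
    for (p in ord) {
      nxt <- cur
      nxt[p] <- ch2[p]
      a1 <- translateCodons(paste0(cur, collapse = ""))
      a2 <- translateCodons(paste0(nxt, collapse = ""))
      if (a2 == "*") return(NULL)
      if (a1 == a2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(paths, count_path)
  valid <- Filter(Negate(is.null), res)
  if (!length(valid)) {
    # all pathways pass a stop: fall back to all pathways, stop steps
    # counted as nonsynonymous
    res <- lapply(paths, function(ord) {
      cur <- ch1
      s <- 0
      n <- 0
      for (p in ord) {
        nxt <- cur
        nxt[p] <- ch2[p]
        a1 <- translateCodons(paste0(cur, collapse = ""))
        a2 <- translateCodons(paste0(nxt, collapse = ""))
        if (a1 != "*" && a1 == a2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    })
    valid <- res
  }
  m <- do.call(rbind, valid)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

.permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

.jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  dim(out) <- dim(p)
  out
}

#' Nei-Gojobori pairwise dN/dS
#'
#' @param seq1,seq2 in-frame nucleotide sequences of equal length (no
#'   internal stops), or single-row codon matrices.
#' @param jc apply the Jukes-Cantor correction (default TRUE). With
#'   `jc = TRUE` a proportion of differences >= 0.75 raises a saturation
#'   error; with `jc = FALSE` the raw counts and proportions are returned
#'   and `dN`/`dS` are NA where undefined.
#' @return named numeric vector: `N`, `S` (potential sites, averaged over
#'   the two sequences), `Nd`, `Sd` (observed differences averaged over
#'   minimal pathways), `pN`, `pS`, `dN`, `dS` (Jukes-Cantor corrected).
#' @examples
#' ng86Pairwise("TTTTTA", "TTATTA")
#' @export
ng86Pairwise <- function(seq1, seq2, jc = TRUE) {
  cm <- .toCodonMatrix(c(a = seq1, b = seq2))
  comp <- .ng86PairCodons(cm[1, ], cm[2, ])
  S <- sum(comp$S)
  N <- sum(comp$N)
  Sd <- sum(comp$Sd)
  Nd <- sum(comp$Nd)
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (jc && (pS >= 0.75 || pN >= 0.75))
    stop("saturation error: proportion of differences >= 0.75")
  c(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
    dN = .jc_correct(pN), dS = .jc_correct(pS))
}

# per-codon decomposition for a pair of codon vectors
.ng86PairCodons <- function(cod1, cod2) {
  nc <- length(cod1)
  S <- N <- Sd <- Nd <- numeric(nc)
  for (k in seq_len(nc)) {
    s1 <- .codonSites(cod1[k])
    s2 <- .codonSites(cod2[k])
    S[k] <- (s1["S"] + s2["S"]) / 2
    N[k] <- (s1["N"] + s2["N"]) / 2
    d <- .codonDiffs(cod1[k], cod2[k])
    Sd[k] <- d["Sd"]
    Nd[k] <- d["Nd"]
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Partitioned average dN/dS with bootstrap standard errors
#'
#' Mean pairwise Nei-Gojobori rates over all sequence pairs, restricted to
#' a codon partition (all, ABS or non-ABS codons), with standard errors
#' from a codon-resampling bootstrap. Bootstrap replicates in which the JC
#' correction is undefined are dropped from the SE computation.
#'
#' @param aln a [CodonAlignment-class].
#' @param partition "all", "ABS", "nonABS", or an integer vector of 1-based
#'   codon indices.
#' @param bootstrap_reps bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list of class `ngResult`: partition, dN, dS, SE_dN, SE_dS, Z,
#'   one-tailed p, and the bootstrap SE of (dN - dS).
#' @export
partitionRates <- function(aln, partition = "all", bootstrap_reps = 1000,
                           seed = 1) {
  cm <- codonMatrix(aln)
  idx <- if (is.numeric(partition)) as.integer(partition)
  else switch(partition,
    all = seq_len(ncol(cm)),
    ABS = absMask(aln),
    nonABS = setdiff(seq_len(ncol(cm)), absMask(aln)),
    stop("unknown partition")
  )
  if (!length(idx)) stop("partition is empty")
  if (length(idx) < 3)
    warning("partition smaller than 3 codons; expect wide standard errors")
  ntaxa <- nrow(cm)
  if (ntaxa < 2) stop("need at least two sequences")
  pairs <- combn(ntaxa, 2)
  np <- ncol(pairs)
  nc <- length(idx)
  Sarr <- Narr <- SdArr <- NdArr <- matrix(0, np, nc)
  for (j in seq_len(np)) {
    comp <- .ng86PairCodons(cm[pairs[1, j], idx], cm[pairs[2, j], idx])
    Sarr[j, ] <- comp$S
    Narr[j, ] <- comp$N
    SdArr[j, ] <- comp$Sd
    NdArr[j, ] <- comp$Nd
  }
  mean_rates <- function(W) {
    # W: nc x nrep matrix of codon multiplicities
    pS <- (SdArr %*% W) / (Sarr %*% W)
    pN <- (NdArr %*% W) / (Narr %*% W)
    dS <- .jc_correct(pS)
    dN <- .jc_correct(pN)
    rbind(dN = colMeans(dN), dS = colMeans(dS))
  }
  point <- mean_rates(matrix(1, nc, 1))
  if (any(is.na(point)))
    stop("saturation error: JC correction undefined for some pair")
  set.seed(seed)
  W <- matrix(0, nc, bootstrap_reps)
  for (r in seq_len(bootstrap_reps)) {
    W[, r] <- tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc)
  }
  boots <- mean_rates(W)
  ok <- !is.na(boots["dN", ]) & !is.na(boots["dS", ])
  se_dN <- sd(boots["dN", ok])
  se_dS <- sd(boots["dS", ok])
  se_diff <- sd(boots["dN", ok] - boots["dS", ok])
  res <- list(partition = if (is.numeric(partition)) "custom" else partition,
    n_codons = nc, dN = unname(point["dN", 1]), dS = unname(point["dS", 1]),
    SE_dN = se_dN, SE_dS = se_dS, SE_diff = se_diff,
    bootstrap_reps = bootstrap_reps)
  z <- zTestSelection(res)
  res$Z <- z[["Z"]]
  res$p <- z[["p"]]
  class(res) <- "ngResult"
  res
}

#' @export
print.ngResult <- function(x, ...) {
  cat(sprintf("NG86 partition %s (%d codons): dN = %.3f (%.3f), dS = %.3f (%.3f), Z = %.3f, p = %.3f\n",
    x$partition, x$n_codons, x$dN, x$SE_dN, x$dS, x$SE_dS, x$Z, x$p))
  invisible(x)
}

#' One-tailed Z-test of positive selection
#'
#' Z = (dN - dS) / SE(dN - dS) with the bootstrap SE of the difference; the
#' one-tailed p is the upper normal tail, reported as 1 when there is no
#' excess of nonsynonymous substitutions (Z <= 0), matching the reporting
#' convention of standard dN/dS software. Zero variance yields Z = 0, p = 1
#' with a flag.
#'
#' @param result list from [partitionRates()].
#' @return named vector `Z`, `p` (and attribute `degenerate` when the SE
#'   was zero).
#' @export
zTestSelection <- function(result) {
  se <- result$SE_diff
  if (is.na(se) || se == 0) {
    out <- c(Z = 0, p = 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (result$dN - result$dS) / se
  p <- if (z <= 0) 1 else 1 - pnorm(z)
  c(Z = z, p = p)
}
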