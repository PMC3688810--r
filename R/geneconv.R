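# Gene-conversion fragment detection in the style of Sawyer's method: on
# the polymorphic columns of the alignment, an inner fragment for a pair of
# sequences is a maximal run of agreement bounded by discordant sites or
# alignment ends; an outer fragment for one sequence is a maximal run of
# otherwise-monomorphic sites at which it differs from every other
# sequence. Fragment scores
# are the number of polymorphic sites spanned (no mismatches allowed within
# a fragment, the original program's default); significance comes from
# permuting the order of the polymorphic columns.

.polymorphicColumns <- function(smat) {
  which(apply(smat, 2, function(col) length(unique(col)) > 1))
}

.seqCharMatrix <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

# maximal runs of TRUE in x; returns data.frame(start, end, len) in
# condensed (polymorphic-site) indices
.runs_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Find candidate inner gene-conversion fragments
#'
#' For every sequence pair, reports the maximal runs of agreement over
#' polymorphic columns, delimited by discordant sites or the alignment
#' ends, with boundaries mapped back to 1-based alignment coordinates.
#'
#' @param seqs named character vector of aligned sequences (>= 3).
#' @param min_sites minimum number of polymorphic sites per reported
#'   fragment (default 2).
#' @return data.frame with columns `seq1`, `seq2`, `start`, `end`
#'   (alignment columns), `score` (polymorphic sites spanned), sorted by
#'   decreasing score. Empty (with a warning) if no polymorphic sites.
#' @export
findInnerFragments <- function(seqs, min_sites = 2) {
  if (length(seqs) < 3) stop("need >= 3 sequences")
  smat <- .seqCharMatrix(seqs)
  poly <- .polymorphicColumns(smat)
  empty <- data.frame(seq1 = character(), seq2 = character(),
    start = integer(), end = integer(), score = integer())
  if (!length(poly)) {
    warning("no polymorphic sites in alignment")
    return(empty)
  }
  pm <- smat[, poly, drop = FALSE]
  prs <- combn(length(seqs), 2)
  out <- list()
  for (j in seq_len(ncol(prs))) {
    i1 <- prs[1, j]
    i2 <- prs[2, j]
    agree <- pm[i1, ] == pm[i2, ]
    runs <- .runs_true(agree)
    runs <- runs[runs$len >= min_sites, , drop = FALSE]
    if (nrow(runs)) {
      out[[length(out) + 1]] <- data.frame(
        seq1 = names(seqs)[i1], seq2 = names(seqs)[i2],
        start = poly[runs$start], end = poly[runs$end],
        score = runs$len, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res[order(-res$score), , drop = FALSE]
}

# columns monomorphic in all sequences except i, with the indicator of
# sequence i differing there (its "unique" sites)
.outer_indicator <- function(smat, i) {
  rest <- smat[-i, , drop = FALSE]
  mono <- apply(rest, 2, function(col) length(unique(col)) == 1)
  cols <- which(mono)
  diff <- smat[i, cols] != rest[1, cols]
  list(cols = cols, diff = unname(diff))
}

#' Find candidate outer gene-conversion fragments
#'
#' For each sequence, considers the columns at which all remaining
#' sequences agree, and reports maximal runs of such columns where the
#' focal sequence differs from the rest (evidence of conversion from a
#' source outside the alignment). Columns polymorphic among the remaining
#' sequences neither extend nor break a run.
#'
#' @inheritParams findInnerFragments
#' @return data.frame with columns `seq`, `start`, `end`, `score`.
#' @export
findOuterFragments <- function(seqs, min_sites = 2) {
  if (length(seqs) < 3) stop("need >= 3 sequences")
  smat <- .seqCharMatrix(seqs)
  poly <- .polymorphicColumns(smat)
  empty <- data.frame(seq = character(), start = integer(), end = integer(),
    score = integer())
  if (!length(poly)) {
    warning("no polymorphic sites in alignment")
    return(empty)
  }
  out <- list()
  for (i in seq_along(seqs)) {
    ind <- .outer_indicator(smat, i)
    runs <- .runs_true(ind$diff)
    runs <- runs[runs$len >= min_sites, , drop = FALSE]
    if (nrow(runs)) {
      out[[length(out) + 1]] <- data.frame(
        seq = names(seqs)[i], start = ind$cols[runs$start],
        end = ind$cols[runs$end], score = runs$len,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res[order(-res$score), , drop = FALSE]
}

.pair_max_runs <- function(agree_mat, perm) {
  # agree_mat: npairs x npoly logical; returns per-pair max run length
  apply(agree_mat[, perm, drop = FALSE], 1, function(x) {
    r <- rle(x)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
}

#' Permutation significance for gene-conversion fragments
#'
#' Permutes the order of the polymorphic columns (preserving per-column
#' content, the method's null of site-order randomness) and scores each
#' permutation by the maximal fragment length. `sim_p` for each observed
#' hit is the rank of its score among the permutation null of the global
#' maximum; `bc_ka_p` is the per-pair (or per-sequence) permutation
#' p-value Bonferroni-scaled by the number of pairs (sequences), a
#' permutation stand-in for the original Karlin-Altschul pairwise
#' p-values.
#'
#' @param seqs the aligned sequences the hits were computed from.
#' @param inner data.frame from [findInnerFragments()] (or NULL).
#' @param outer data.frame from [findOuterFragments()] (or NULL).
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed.
#' @return list with `inner`, `outer` (hits augmented with `sim_p` and
#'   `bc_ka_p`), and `global_inner_p`, `global_outer_p` (sim p of the
#'   observed global maxima).
#' @export
permutationSignificance <- function(seqs, inner = NULL, outer = NULL,
                                    n_perm = 10000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  smat <- .seqCharMatrix(seqs)
  poly <- .polymorphicColumns(smat)
  npoly <- length(poly)
  pm <- smat[, poly, drop = FALSE]
  res <- list(inner = inner, outer = outer,
    global_inner_p = NA_real_, global_outer_p = NA_real_)
  if (!npoly) return(res)

  if (!is.null(inner)) {
    prs <- combn(length(seqs), 2)
    agree <- t(vapply(seq_len(ncol(prs)), function(j)
      pm[prs[1, j], ] == pm[prs[2, j], ], logical(npoly)))
    null_pair <- matrix(0L, n_perm, nrow(agree))
    for (r in seq_len(n_perm)) {
      null_pair[r, ] <- .pair_max_runs(agree, sample.int(npoly))
    }
    null_global <- apply(null_pair, 1, max)
    pairkey <- paste(names(seqs)[prs[1, ]], names(seqs)[prs[2, ]])
    if (nrow(inner)) {
      hk <- match(paste(inner$seq1, inner$seq2), pairkey)
      inner$sim_p <- vapply(inner$score, function(s)
        (1 + sum(null_global >= s)) / (n_perm + 1), numeric(1))
      inner$bc_ka_p <- pmin(1, vapply(seq_len(nrow(inner)), function(h)
        (1 + sum(null_pair[, hk[h]] >= inner$score[h])) / (n_perm + 1),
        numeric(1)) * ncol(prs))
      res$inner <- inner
      obs_max <- max(inner$score)
      res$global_inner_p <- (1 + sum(null_global >= obs_max)) / (n_perm + 1)
    } else {
      res$global_inner_p <- 1
    }
  }
  if (!is.null(outer)) {
    # per-sequence restricted indicators (columns monomorphic in the rest);
    # the null permutes each sequence's own indicator ordering
    inds <- lapply(seq_along(seqs), function(i)
      .outer_indicator(smat, i)$diff)
    null_seq <- matrix(0L, n_perm, length(seqs))
    for (r in seq_len(n_perm)) {
      null_seq[r, ] <- vapply(inds, function(x) {
        if (!length(x)) return(0L)
        rl <- rle(x[sample.int(length(x))])
        m <- rl$lengths[rl$values]
        if (length(m)) max(m) else 0L
      }, integer(1))
    }
    null_global <- apply(null_seq, 1, max)
    if (nrow(outer)) {
      hk <- match(outer$seq, names(seqs))
      outer$sim_p <- vapply(outer$score, function(s)
        (1 + sum(null_global >= s)) / (n_perm + 1), numeric(1))
      outer$bc_ka_p <- pmin(1, vapply(seq_len(nrow(outer)), function(h)
        (1 + sum(null_seq[, hk[h]] >= outer$score[h])) / (n_perm + 1),
        numeric(1)) * length(seqs))
      res$outer <- outer
      res$global_outer_p <- (1 + sum(null_global >= max(outer$score))) /
        (n_perm + 1)
    } else {
      res$global_outer_p <- 1
    }
  }
  res
}

#' One-call gene-conversion scan
#'
#' @inheritParams permutationSignificance
#' @param min_sites minimum fragment size in polymorphic sites.
#' @return the [permutationSignificance()] result.
#' @export
geneconvScan <- function(seqs, n_perm = 10000, min_sites = 2, seed = 1) {
  inner <- findInnerFragments(seqs, min_sites)
  outer <- findOuterFragments(seqs, min_sites)
  permutationSignificance(seqs, inner, outer, n_perm = n_perm, seed = seed)
}
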