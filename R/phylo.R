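# Distance-based phylogeny of validated alleles: pairwise distances
# (p-distance or Jukes-Cantor), neighbour-joining, and nonparametric
# bootstrap support over alignment columns.

#' Pairwise distance matrix from an alignment
#'
#' Computes p-distances or Jukes-Cantor corrected distances
#' (d = -(3/4) log(1 - (4/3) p)) between aligned, equal-length sequences.
#' Under the JC model a pair with p >= 0.75 is saturated and the distance is
#' undefined; such pairs raise an error naming the pair.
#'
#' @param seqs named character vector of aligned sequences.
#' @param model "JC" (default) or "p".
#' @return symmetric numeric matrix of distances (substitutions/site).
#' @export
alignmentDistances <- function(seqs, model = c("JC", "p")) {
  model <- match.arg(model)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("sequences must be aligned")
  dna <- ape::as.DNAbin(Biostrings::DNAStringSet(seqs))
  p <- as.matrix(ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE))
  if (model == "p") return(p)
  if (any(p >= 0.75)) {
    bad <- which(p >= 0.75, arr.ind = TRUE)[1, ]
    stop("saturation error: p >= 0.75 for pair ",
      rownames(p)[bad[1]], " / ", colnames(p)[bad[2]])
  }
  d <- -0.75 * log(1 - (4 / 3) * p)
  d[abs(d) < 1e-15] <- 0
  d
}

#' Neighbour-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix; negative branch
#' length estimates are clamped to zero and flagged via an attribute.
#'
#' @param dm symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An `ape::phylo` tree; attribute `clamped` gives the number of
#'   negative branch lengths set to zero.
#' @export
njTree <- function(dm) {
  if (nrow(dm) < 3) stop("size error: NJ needs at least 3 taxa")
  tr <- ape::nj(as.dist(dm))
  n_neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- n_neg
  tr
}

#' Bootstrap support for NJ bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' percentage of replicates containing the same bipartition.
#'
#' @param seqs named character vector of aligned sequences.
#' @param replicates bootstrap replicates (default 1000).
#' @param model distance model passed to [alignmentDistances()].
#' @param seed integer seed.
#' @param min_support only supports strictly above this value are retained
#'   as node labels (default 50, i.e. ">50% shown"); pass 0 to keep all.
#' @return the NJ tree with `node.label` holding supports (%); attribute
#'   `support` carries the unfiltered support vector.
#' @export
bootstrapSupport <- function(seqs, replicates = 1000, model = "JC",
                             seed = 1, min_support = 50) {
  set.seed(seed)
  L <- nchar(seqs[1])
  tr <- njTree(alignmentDistances(seqs, model))
  smat <- do.call(rbind, strsplit(seqs, ""))
  rownames(smat) <- names(seqs)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    bs <- apply(smat[, cols, drop = FALSE], 1, paste0, collapse = "")
    reps[[r]] <- tryCatch(njTree(alignmentDistances(bs, model)),
      error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(tr, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(reps), 1)
  tr$node.label <- ifelse(support > min_support, support, "")
  attr(tr, "support") <- support
  tr
}
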