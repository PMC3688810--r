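# Design of 7-bp multiplexing tags for dual-indexed amplicon sequencing.
# Tags must avoid homopolymers (error-prone in pyrosequencing chemistry),
# avoid tandem motif repeats, and keep pairwise Hamming distance >= 3 so a
# single sequencing error cannot convert one tag into another.

#' Hamming distance between equal-length strings
#'
#' @param a,b character strings of equal length.
#' @return Integer number of mismatching positions.
#' @export
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

.hasHomopolymer <- function(chars) any(chars[-1] == chars[-length(chars)])

# tandem repeat of any motif of length >= 2 anywhere in the tag
.hasTandemMotif <- function(chars) {
  n <- length(chars)
  for (m in 2:floor(n / 2)) {
    for (s in seq_len(n - 2 * m + 1)) {
      if (all(chars[s:(s + m - 1)] == chars[(s + m):(s + 2 * m - 1)]))
        return(TRUE)
    }
  }
  FALSE
}

#' Enumerate candidate multiplexing tags
#'
#' Enumerates, in lexicographic order (A < C < G < T), all tags of the given
#' length over the DNA alphabet passing the per-tag predicates:
#' no homopolymer (no two identical adjacent bases) and, optionally, no
#' tandem repetition of any motif of length >= 2.
#'
#' @param length tag length in nucleotides (default 7).
#' @param no_homopolymer reject tags containing two identical adjacent bases.
#' @param no_motif_repeat reject tags containing a tandem motif repeat.
#' @return Character vector of candidate tags, lexicographically sorted.
#' @examples
#' length(enumerateCandidateTags(4))
#' @export
enumerateCandidateTags <- function(length = 7, no_homopolymer = TRUE,
                                   no_motif_repeat = TRUE) {
  stopifnot(length >= 1)
  alph <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
    c(rep(list(alph), length), stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reverse for lexicographic
  grid <- grid[, rev(seq_len(length)), drop = FALSE]
  chars <- as.matrix(grid)
  keep <- rep(TRUE, nrow(chars))
  if (no_homopolymer && length >= 2) {
    keep <- keep & !apply(chars, 1, .hasHomopolymer)
  }
  if (no_motif_repeat && length >= 4) {
    keep <- keep & !apply(chars, 1, .hasTandemMotif)
  }
  tags <- apply(chars[keep, , drop = FALSE], 1, paste0, collapse = "")
  sort(tags)
}

#' Select a mutually compatible tag set
#'
#' Greedy maximum-distance accretion: candidates are scanned (optionally in a
#' seed-shuffled order) and a tag is kept if its Hamming distance to every
#' tag already kept is at least `min_hamming`. With several restarts the
#' largest set found is returned. The code size required here (>= 40 tags at
#' distance 3 over 7-mers) is far below coding-theory limits, so the greedy
#' construction always succeeds at the default settings.
#'
#' @param candidates character vector of candidate tags (equal length).
#' @param min_hamming minimum pairwise Hamming distance (default 3).
#' @param target_size required number of tags (default 40).
#' @param seed integer seed controlling restart shuffles.
#' @param restarts number of randomized restarts after the lexicographic pass.
#' @return Character vector of selected tags with all pairwise distances
#'   >= `min_hamming`. Errors if `target_size` cannot be reached, reporting
#'   the best size found.
#' @export
selectTagSet <- function(candidates, min_hamming = 3, target_size = 40,
                         seed = 1, restarts = 3) {
  stopifnot(length(candidates) >= 1)
  len <- nchar(candidates[1])
  if (min_hamming > len) stop("min_hamming exceeds tag length")
  cmat <- matrix(unlist(strsplit(candidates, "")), ncol = len, byrow = TRUE)

  greedy <- function(ord) {
    sel <- integer(0)
    for (i in ord) {
      if (!length(sel)) {
        sel <- i
        next
      }
      d <- rowSums(cmat[sel, , drop = FALSE] !=
        matrix(cmat[i, ], length(sel), len, byrow = TRUE))
      if (all(d >= min_hamming)) sel <- c(sel, i)
    }
    sel
  }

  best <- greedy(seq_along(candidates))
  if (length(best) < target_size && restarts > 0) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      sel <- greedy(sample(seq_along(candidates)))
      if (length(sel) > length(best)) best <- sel
      if (length(best) >= target_size) break
    }
  }
  if (length(best) < target_size) {
    stop("could not reach target_size = ", target_size,
      "; best set found has ", length(best), " tags")
  }
  candidates[sort(best)]
}

#' Lay out forward x reverse tag combinations on a 96-well plate
#'
#' Assigns each specimen a unique (forward tag, reverse tag) pair by filling
#' an `n_forward` x `n_reverse` grid row-major, mirroring a plate with
#' tag-modified forward primers in rows and reverse primers in columns.
#'
#' @param tagset character vector of validated tags.
#' @param n_forward number of forward-tagged primers (default 12).
#' @param n_reverse number of reverse-tagged primers (default 8).
#' @param specimens character vector of specimen ids
#'   (at most `n_forward * n_reverse`).
#' @return data.frame with columns `well`, `forward_tag`, `reverse_tag`,
#'   `specimen`; unused wells carry `NA` specimens.
#' @export
buildPlateLayout <- function(tagset, n_forward = 12, n_reverse = 8,
                             specimens) {
  if (n_forward + n_reverse > length(tagset))
    stop("tagset too small for requested forward+reverse primers")
  if (length(specimens) > n_forward * n_reverse)
    stop("capacity error: ", length(specimens), " specimens exceed ",
      n_forward * n_reverse, " wells")
  fwd <- tagset[seq_len(n_forward)]
  rev <- tagset[n_forward + seq_len(n_reverse)]
  grid <- expand.grid(f = seq_len(n_forward), r = seq_len(n_reverse))
  grid <- grid[order(grid$f, grid$r), ]
  layout <- data.frame(
    well = paste0(LETTERS[(grid$f - 1) %% 26 + 1], grid$r),
    forward_tag = fwd[grid$f],
    reverse_tag = rev[grid$r],
    specimen = NA_character_,
    stringsAsFactors = FALSE
  )
  layout$specimen[seq_along(specimens)] <- specimens
  layout
}

#' Read or write a plate layout CSV
#'
#' @param layout plate layout data.frame from [buildPlateLayout()].
#' @param path CSV file path.
#' @return `readPlateLayout` returns the layout data.frame.
#' @export
writePlateLayout <- function(layout, path) {
  write.csv(layout, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePlateLayout
#' @export
readPlateLayout <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
    colClasses = c(specimen = "character"))
}

#' DAB marker primers and amplicon arithmetic
#'
#' `dabPrimers()` returns the genotyping primers for the DAB1-like and
#' DAB3-like exon-2 markers together with their annealing positions on the
#' carp reference genes (1-based, position of the 5'-most base of each
#' primer binding site on the plus strand). `ampliconLength()` computes the
#' PCR product length implied by those coordinates, optionally with 7-bp
#' tags on both primers.
#'
#' @return `dabPrimers()`: data.frame with one row per marker and columns
#'   `marker`, `forward`, `reverse`, `fwd_pos`, `rev_pos`.
#' @export
dabPrimers <- function() {
  data.frame(
    marker = c("DAB1", "DAB3"),
    forward = c("CTGCTTTCACTGGAGCAGCTA", "GCTTTCACTGGAACAGCTG"),
    reverse = c("GTCTGCCACCAGCCTGAG", "ACAGCTGGATGATTGCCTT"),
    fwd_pos = c(48L, 33L),
    rev_pos = c(372L, 364L),
    stringsAsFactors = FALSE
  )
}

#' @rdname dabPrimers
#' @param fwd_pos,rev_pos 1-based plus-strand positions of the 5'-most base
#'   of the forward and reverse primer binding sites.
#' @param rev_len reverse primer length in nt.
#' @param tag_length length of the tag added to each primer (0 = untagged).
#' @export
ampliconLength <- function(fwd_pos, rev_pos, rev_len, tag_length = 0) {
  (rev_pos - fwd_pos) + rev_len + 2L * tag_length
}
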