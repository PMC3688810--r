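# Shared codon machinery: the 61 sense codons of the standard genetic code,
# codon <-> index maps, and the single-substitution type matrix used by the
# Muse/Goldman-Yang style rate matrix.

NUC <- c("T", "C", "A", "G")

.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' Returns the 61 non-stop codons (standard code) in a fixed order
#' (T < C < A < G by position, the conventional codon-model ordering).
#'
#' @return Character vector of length 61.
#' @export
senseCodons <- function() {
  if (is.null(.codon_env$codons)) .initCodonTables()
  .codon_env$codons
}

#' Translate codons to amino acids
#'
#' @param codons character vector of 3-letter codons (standard code).
#' @return Character vector of one-letter amino acids ("*" for stop).
#' @export
translateCodons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[toupper(codons)])
}

.initCodonTables <- function() {
  all3 <- as.vector(outer(outer(NUC, NUC, paste0), NUC, paste0))
  # order with position 1 slowest: build explicitly
  all3 <- character(64)
  k <- 1
  for (a in NUC) for (b in NUC) for (d in NUC) {
    all3[k] <- paste0(a, b, d)
    k <- k + 1
  }
  aa <- translateCodons(all3)
  keep <- aa != "*"
  codons <- all3[keep]
  .codon_env$codons <- codons
  .codon_env$aa <- aa[keep]
  .codon_env$index <- setNames(seq_along(codons), codons)

  n <- length(codons)
  type <- matrix(0L, n, n)
  m1 <- matrix(unlist(strsplit(codons, "")), nrow = n, byrow = TRUE)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diffs <- which(m1[i, ] != m1[j, ])
      if (length(diffs) != 1L) next
      ts <- transitions[[m1[i, diffs]]] == m1[j, diffs]
      syn <- .codon_env$aa[i] == .codon_env$aa[j]
      type[i, j] <- if (syn) {
        if (ts) 2L else 1L
      } else {
        if (ts) 4L else 3L
      }
    }
  }
  .codon_env$pairType <- type
  invisible(NULL)
}

codonPairType <- function() {
  if (is.null(.codon_env$pairType)) .initCodonTables()
  .codon_env$pairType
}

codonIndex <- function(codons) {
  if (is.null(.codon_env$index)) .initCodonTables()
  idx <- .codon_env$index[toupper(codons)]
  unname(idx)
}

# Split equal-length in-frame sequences into a codon character matrix
# (ntaxa x ncodon). Stops on internal stop codons unless allow_stop.
.toCodonMatrix <- function(seqs, allow_stop = FALSE) {
  nms <- names(seqs)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- nms
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must be aligned to equal length")
  if (lens[1] %% 3 != 0L)
    stop("alignment length ", lens[1], " is not divisible by 3 (frame error)")
  nc <- lens[1] / 3L
  cm <- matrix("", length(seqs), nc)
  for (i in seq_along(seqs)) {
    cm[i, ] <- substring(seqs[i], 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  }
  if (!allow_stop) {
    aa <- translateCodons(cm)
    if (any(aa == "*", na.rm = TRUE))
      stop("internal stop codon in input sequences")
  }
  rownames(cm) <- names(seqs)
  cm
}

#' Empirical codon frequencies (F3x4)
#'
#' Computes the F3x4 codon frequency vector: the product of empirical
#' nucleotide frequencies at each codon position, renormalized over the 61
#' sense codons. Frequencies are floored at a small positive value so the
#' substitution process stays irreducible on sparse alignments.
#'
#' @param codonmat character matrix of codons (taxa x sites).
#' @param floor minimum codon frequency before renormalization.
#' @return Numeric vector of length 61, summing to 1, named by codon.
#' @export
codonFreqF3x4 <- function(codonmat, floor = 1e-6) {
  pos <- lapply(1:3, function(p) {
    b <- substring(as.vector(codonmat), p, p)
    tab <- table(factor(b, levels = NUC))
    f <- as.numeric(tab) / sum(tab)
    setNames(pmax(f, 1e-4) / sum(pmax(f, 1e-4)), NUC)
  })
  codons <- senseCodons()
  pi0 <- vapply(codons, function(cd) {
    pos[[1]][substr(cd, 1, 1)] * pos[[2]][substr(cd, 2, 2)] *
      pos[[3]][substr(cd, 3, 3)]
  }, numeric(1))
  pi0 <- pmax(pi0, floor)
  pi0 / sum(pi0)
}
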