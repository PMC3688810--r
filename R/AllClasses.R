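# Central S4 containers. Sequence payloads are plain character vectors or
# Biostrings objects; tabular payloads are data.frames so they round-trip
# through TSV losslessly.

#' AllelePool: a simulated pool of DAB exon-2 alleles
#'
#' Holds the ground-truth allele sequences of a synthetic study: allele ids,
#' lineage labels (DAB1/DAB3), nucleotide sequences (the exon-2 core), and a
#' species-assignment map (`A`, `B` or `shared`) per allele.
#'
#' @slot sequences named character vector of allele nucleotide sequences.
#' @slot lineage named character vector, values in `c("DAB1","DAB3")`.
#' @slot speciesAssignment named character vector, values in
#'   `c("A","B","shared")`.
#' @slot exon2Length integer, length in bp of every sequence.
#' @exportClass AllelePool
setClass("AllelePool",
  representation(
    sequences = "character",
    lineage = "character",
    speciesAssignment = "character",
    exon2Length = "integer"
  )
)

setValidity("AllelePool", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@lineage))
    msg <- c(msg, "sequences and lineage lengths differ")
  if (any(nchar(object@sequences) != object@exon2Length))
    msg <- c(msg, "not all sequences have exon2Length bp")
  if (object@exon2Length %% 3L != 0L)
    msg <- c(msg, "exon2Length not divisible by 3")
  if (!all(object@lineage %in% c("DAB1", "DAB3")))
    msg <- c(msg, "lineage values must be DAB1 or DAB3")
  if (!all(object@speciesAssignment %in% c("A", "B", "shared")))
    msg <- c(msg, "speciesAssignment values must be A, B or shared")
  aa <- tryCatch(
    translateCodons(.toCodonMatrix(object@sequences, allow_stop = TRUE)),
    error = function(e) NULL
  )
  if (!is.null(aa) && any(aa == "*"))
    msg <- c(msg, "in-frame stop codon in allele sequence")
  if (length(msg)) msg else TRUE
})

#' @describeIn AllelePool Number of alleles in the pool.
#' @param x,object an `AllelePool`.
#' @export
setMethod("length", "AllelePool", function(x) length(x@sequences))

setMethod("show", "AllelePool", function(object) {
  cat("AllelePool with", length(object), "alleles (",
    sum(object@lineage == "DAB1"), "DAB1-like,",
    sum(object@lineage == "DAB3"), "DAB3-like ),",
    object@exon2Length, "bp exon-2 core\n")
  cat("species assignment:",
    paste(names(table(object@speciesAssignment)),
      table(object@speciesAssignment),
      sep = "=", collapse = ", "), "\n")
})

#' Accessors for AllelePool
#'
#' @param pool an [AllelePool-class] object.
#' @return `alleleSequences()` the named sequence vector; `alleleLineages()`
#'   the lineage per allele; `speciesAssignment()` the species map.
#' @export
alleleSequences <- function(pool) pool@sequences

#' @rdname alleleSequences
#' @export
alleleLineages <- function(pool) pool@lineage

#' @rdname alleleSequences
#' @export
speciesAssignment <- function(pool) pool@speciesAssignment

#' VariantTable: per-amplicon read counts and MPAF per sequence variant
#'
#' One row per distinct (marker, variant sequence); the `counts` slot is a
#' variant x amplicon integer matrix of read counts, `freqs` the
#' within-amplicon frequencies. `MPAF` is the maximum per-amplicon frequency
#' of the variant over all amplicons in which it occurs; `status` holds the
#' validation outcome after [classifyAndCall()].
#'
#' @slot variants data.frame with columns `variant_id`, `marker`, `sequence`,
#'   `mpaf`, `n_amplicons`, `status`.
#' @slot counts integer matrix (variants x amplicons).
#' @slot amplicons data.frame with columns `amplicon_id`, `specimen`,
#'   `marker`, `n_reads`.
#' @exportClass VariantTable
setClass("VariantTable",
  representation(
    variants = "data.frame",
    counts = "matrix",
    amplicons = "data.frame"
  )
)

setValidity("VariantTable", function(object) {
  msg <- character()
  if (nrow(object@variants) != nrow(object@counts))
    msg <- c(msg, "variants rows must match counts rows")
  if (nrow(object@amplicons) != ncol(object@counts))
    msg <- c(msg, "amplicons rows must match counts columns")
  cs <- colSums(object@counts)
  if (any(cs != object@amplicons$n_reads))
    msg <- c(msg, "column sums of counts must equal amplicon read counts")
  if (nrow(object@variants) &&
      (any(object@variants$mpaf <= 0) || any(object@variants$mpaf > 1)))
    msg <- c(msg, "MPAF must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable:", nrow(object@variants), "variants across",
    nrow(object@amplicons), "amplicons\n")
  if (nrow(object@variants)) {
    print(table(object@variants$status))
  }
})

#' Accessors for VariantTable
#'
#' @param x a [VariantTable-class].
#' @return `variantInfo()` the per-variant data.frame; `variantCounts()` the
#'   variant x amplicon count matrix; `ampliconInfo()` amplicon metadata.
#' @export
variantInfo <- function(x) x@variants

#' @rdname variantInfo
#' @export
variantCounts <- function(x) x@counts

#' @rdname variantInfo
#' @export
ampliconInfo <- function(x) x@amplicons

#' AlleleCatalog: validated, named alleles
#'
#' @slot table data.frame with columns `name`, `sequence`, `lineage`,
#'   `occurrence` (comma-collapsed species set, subset of `A`,`B`,`hybrid`).
#' @exportClass AlleleCatalog
setClass("AlleleCatalog", representation(table = "data.frame"))

setValidity("AlleleCatalog", function(object) {
  tb <- object@table
  msg <- character()
  if (anyDuplicated(tb$name)) msg <- c(msg, "allele names must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlleleCatalog", function(object) {
  cat("AlleleCatalog with", nrow(object@table), "alleles\n")
  if (nrow(object@table)) print(table(object@table$lineage))
})

#' @rdname variantInfo
#' @export
catalogTable <- function(x) x@table

#' PresenceMatrix: specimen x allele binary matrix treated as dominant loci
#'
#' @slot presence integer matrix (specimens x alleles), entries 0/1.
#' @slot population character vector of population labels per specimen.
#' @exportClass PresenceMatrix
setClass("PresenceMatrix",
  representation(presence = "matrix", population = "character")
)

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  if (!all(object@presence %in% c(0L, 1L)))
    msg <- c(msg, "presence entries must be 0/1")
  if (length(object@population) != nrow(object@presence))
    msg <- c(msg, "one population label per specimen required")
  if (ncol(object@presence) && any(colSums(object@presence) < 1))
    msg <- c(msg, "every allele column must be observed at least once")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@presence), "specimens x",
    ncol(object@presence), "alleles;",
    length(unique(object@population)), "populations\n")
})

#' @rdname variantInfo
#' @export
presence <- function(x) x@presence

#' @rdname variantInfo
#' @export
populations <- function(x) x@population

#' CodonAlignment: an in-frame codon alignment with an optional ABS mask
#'
#' @slot codons character matrix (taxa x codon sites) of codon triplets.
#' @slot absMask integer vector of 1-based codon indices forming the
#'   antigen-binding-site partition (may be empty).
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(codons = "matrix", absMask = "integer")
)

setValidity("CodonAlignment", function(object) {
  msg <- character()
  aa <- translateCodons(object@codons)
  if (any(aa == "*", na.rm = TRUE))
    msg <- c(msg, "internal stop codon in alignment")
  if (length(object@absMask) &&
      (min(object@absMask) < 1 || max(object@absMask) > ncol(object@codons)))
    msg <- c(msg, "ABS mask indices outside codon range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", nrow(object@codons), "sequences x",
    ncol(object@codons), "codons;", length(object@absMask),
    "ABS codons masked\n")
})

#' Build a CodonAlignment from sequences
#'
#' @param seqs named character vector (or `DNAStringSet`) of aligned,
#'   equal-length, in-frame nucleotide sequences without internal stops.
#' @param abs_mask optional integer vector of 1-based ABS codon indices.
#' @return A [CodonAlignment-class] object.
#' @export
codonAlignment <- function(seqs, abs_mask = integer()) {
  cm <- .toCodonMatrix(seqs)
  new("CodonAlignment", codons = cm, absMask = as.integer(abs_mask))
}

#' @rdname codonAlignment
#' @param x a `CodonAlignment`.
#' @export
codonMatrix <- function(x) x@codons

#' @rdname codonAlignment
#' @export
absMask <- function(x) x@absMask

#' SiteModelFit: a fitted codon site model
#'
#' @slot model one of "M0","M1a","M2a","M3","M7","M8".
#' @slot logLik maximized log-likelihood.
#' @slot npar number of free parameters of the omega structure
#'   (M0:1, M1a:2, M2a:4, M3:5, M7:2, M8:4).
#' @slot params named list of parameter estimates (kappa, tree scale, class
#'   proportions and omegas, beta shapes where applicable).
#' @slot siteClassLogLik matrix (classes x sites) of per-site conditional
#'   log-likelihoods at the optimum (used by BEB).
#' @slot classOmega numeric vector of class omega values.
#' @slot classProp numeric vector of class proportions.
#' @slot convergence optimizer convergence code (0 = converged).
#' @exportClass SiteModelFit
setClass("SiteModelFit",
  representation(
    model = "character",
    logLik = "numeric",
    npar = "integer",
    params = "list",
    siteClassLogLik = "matrix",
    classOmega = "numeric",
    classProp = "numeric",
    convergence = "integer"
  )
)

setValidity("SiteModelFit", function(object) {
  msg <- character()
  if (!object@model %in% c("M0", "M1a", "M2a", "M3", "M7", "M8"))
    msg <- c(msg, "unknown model code")
  if (abs(sum(object@classProp) - 1) > 1e-8)
    msg <- c(msg, "class proportions must sum to 1")
  if (any(object@classOmega < 0))
    msg <- c(msg, "omega values must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SiteModelFit", function(object) {
  cat(sprintf("SiteModelFit %s: lnL = %.3f (%d free omega-structure parameters)\n",
    object@model, object@logLik, object@npar))
  cat("  classes: omega =", paste(signif(object@classOmega, 4), collapse = ", "),
    "\n  props =", paste(signif(object@classProp, 4), collapse = ", "), "\n")
})

#' @rdname codonAlignment
#' @param fit a `SiteModelFit`.
#' @export
modelLogLik <- function(fit) fit@logLik

#' @rdname codonAlignment
#' @export
modelParams <- function(fit) fit@params
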