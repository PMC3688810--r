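# Demultiplexing, variant tabulation, MPAF-based allele validation and
# nomenclature. The validation statistic is the maximum per-amplicon
# frequency (MPAF): a variant's largest within-amplicon read fraction over
# all amplicons in which it occurs. Low-MPAF variants explainable as a
# single substitution from, or a single-crossover recombinant of,
# higher-frequency variants in the same amplicon are artefacts; variants at
# or above the acceptance threshold in some amplicon are true alleles.

.char_int <- function(seqs) {
  # sequences (equal length) -> integer matrix, A/C/G/T -> 1..4, other 0
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  mi <- matrix(match(m, c("A", "C", "G", "T"), nomatch = 0L),
    nrow = nrow(m))
  mi
}

#' Demultiplex tagged reads to wells
#'
#' Extracts the 7-bp forward tag (read start) and reverse tag
#' (reverse-complemented read end) and assigns each read to the unique well
#' whose tag pair matches within `allow_mismatch` substitutions on each tag.
#' Reads with an unmatched or ambiguous tag (two wells within tolerance) go
#' to the unassigned pool with a reason.
#'
#' @param reads named character vector of read sequences.
#' @param layout plate layout data.frame (`well`, `forward_tag`,
#'   `reverse_tag`, `specimen`), tags already validated.
#' @param allow_mismatch maximum substitutions tolerated per tag (default 0).
#' @return list with `assigned` (data.frame read, well, specimen) and
#'   `unassigned` (data.frame read, reason).
#' @export
demultiplexReads <- function(reads, layout, allow_mismatch = 0) {
  lay <- layout[!is.na(layout$specimen), , drop = FALSE]
  taglen <- nchar(lay$forward_tag[1])
  f_obs <- substr(reads, 1, taglen)
  r_obs_rc <- substr(reads, nchar(reads) - taglen + 1, nchar(reads))
  r_obs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r_obs_rc)))

  match_tag <- function(obs, tags) {
    utags <- unique(tags)
    om <- .char_int(obs)
    best <- rep(NA_character_, length(obs))
    bestd <- rep(Inf, length(obs))
    ambig <- rep(FALSE, length(obs))
    for (tg in utags) {
      tv <- match(strsplit(tg, "")[[1]], c("A", "C", "G", "T"), nomatch = 0L)
      d <- rowSums(om != matrix(tv, nrow(om), taglen, byrow = TRUE))
      better <- d < bestd
      tie <- d == bestd & d <= allow_mismatch
      ambig[tie] <- TRUE
      ambig[better] <- FALSE
      best[better] <- tg
      bestd[better] <- d[better]
    }
    ok <- bestd <= allow_mismatch & !ambig
    list(tag = ifelse(ok, best, NA_character_),
      ambiguous = ambig & bestd <= allow_mismatch)
  }
  fm <- match_tag(f_obs, lay$forward_tag)
  rm_ <- match_tag(r_obs, lay$reverse_tag)
  key <- paste(fm$tag, rm_$tag)
  laykey <- paste(lay$forward_tag, lay$reverse_tag)
  widx <- match(key, laykey)
  ok <- !is.na(fm$tag) & !is.na(rm_$tag) & !is.na(widx)
  reason <- rep(NA_character_, length(reads))
  reason[is.na(fm$tag) & !fm$ambiguous] <- "forward tag unmatched"
  reason[is.na(rm_$tag) & !rm_$ambiguous] <- "reverse tag unmatched"
  reason[fm$ambiguous | rm_$ambiguous] <- "ambiguous tag"
  reason[!ok & is.na(reason)] <- "tag pair not on plate"
  list(
    assigned = data.frame(read = names(reads)[ok], well = lay$well[widx[ok]],
      specimen = lay$specimen[widx[ok]], stringsAsFactors = FALSE),
    unassigned = data.frame(read = names(reads)[!ok], reason = reason[!ok],
      stringsAsFactors = FALSE)
  )
}

#' Assign a sequence to a DAB marker by reference identity
#'
#' Ungapped global identity against each reference (sequences of unequal
#' length are compared over their common prefix length, penalizing the
#' length difference). The marker of the best-identity reference is returned
#' when identity >= `min_identity`, else `"unassigned"`.
#'
#' @param seqs character vector of template sequences.
#' @param references named character vector of per-marker reference
#'   sequences (names = markers).
#' @param min_identity identity floor (default 0.8).
#' @return character vector of marker labels (or "unassigned").
#' @export
assignMarker <- function(seqs, references, min_identity = 0.8) {
  if (!length(references)) stop("configuration error: empty reference set")
  ids <- sapply(names(references), function(mk) {
    ref <- references[[mk]]
    vapply(seqs, function(s) {
      L <- min(nchar(s), nchar(ref))
      Lmax <- max(nchar(s), nchar(ref))
      if (L == 0) return(0)
      eq <- sum(strsplit(substr(s, 1, L), "")[[1]] ==
        strsplit(substr(ref, 1, L), "")[[1]])
      eq / Lmax
    }, numeric(1), USE.NAMES = FALSE)
  })
  ids <- matrix(ids, nrow = length(seqs))
  best <- max.col(ids, ties.method = "first")
  bestid <- ids[cbind(seq_along(seqs), best)]
  ifelse(bestid >= min_identity, names(references)[best], "unassigned")
}

#' Trim demultiplexed reads to the exon-2 core and bin per amplicon
#'
#' Identifies each read's marker from its forward primer (exact coordinate
#' trimming: tag and primer lengths are known), strips tags, primers and the
#' conserved exon-1/exon-3 flanks, and confirms the marker by reference
#' identity. Reads failing primer recognition or reference identity are
#' dropped.
#'
#' @param reads named character vector.
#' @param assigned data.frame from [demultiplexReads()]`$assigned`.
#' @param references named per-marker interior reference sequences
#'   ([markerReferences()]).
#' @param exon2_length exon-2 core length (default 276).
#' @param max_primer_mismatch maximum mismatches tolerated in the forward
#'   primer when recognizing the marker (default 3).
#' @param min_identity marker-confirmation identity floor (default 0.8).
#' @return data.frame with columns `read`, `specimen`, `marker`, `core`.
#' @export
binReads <- function(reads, assigned, references, exon2_length = 276,
                     max_primer_mismatch = 3, min_identity = 0.8) {
  primers <- dabPrimers()
  cfg <- markerConfig()
  taglen <- 7L
  sub <- reads[assigned$read]
  out <- vector("list", nrow(primers))
  # recognize marker from the forward primer
  pdist <- sapply(seq_len(nrow(primers)), function(i) {
    p <- primers$forward[i]
    obs <- substr(sub, taglen + 1, taglen + nchar(p))
    om <- .char_int(obs)
    tv <- match(strsplit(p, "")[[1]], c("A", "C", "G", "T"), nomatch = 0L)
    rowSums(om != matrix(tv, nrow(om), nchar(p), byrow = TRUE))
  })
  pdist <- matrix(pdist, nrow = length(sub))
  mi <- max.col(-pdist, ties.method = "first")
  okp <- pdist[cbind(seq_along(sub), mi)] <= max_primer_mismatch
  marker <- primers$marker[mi]
  f_len <- nchar(primers$forward)[mi]
  r_len <- nchar(primers$reverse)[mi]
  tmpl <- substr(sub, taglen + f_len + 1, nchar(sub) - taglen - r_len)
  f5 <- nchar(vapply(cfg[marker], `[[`, character(1), "flank5"))
  f3 <- nchar(vapply(cfg[marker], `[[`, character(1), "flank3"))
  core <- substr(tmpl, f5 + 1, nchar(tmpl) - f3)
  conf <- rep("unassigned", length(sub))
  if (any(okp)) {
    conf[okp] <- assignMarker(tmpl[okp], references, min_identity)
  }
  keep <- okp & conf == marker
  data.frame(
    read = assigned$read[keep],
    specimen = assigned$specimen[keep],
    marker = marker[keep],
    core = unname(core[keep]),
    stringsAsFactors = FALSE
  )
}

#' Tabulate sequence variants per amplicon
#'
#' One amplicon per (specimen, marker); one variant row per distinct core
#' sequence within a marker. Computes per-amplicon counts, within-amplicon
#' frequencies, the MPAF, and the number of amplicons each variant occurs
#' in. Empty amplicons are skipped with a warning.
#'
#' @param bins data.frame from [binReads()] (columns `specimen`, `marker`,
#'   `core`).
#' @return A [VariantTable-class].
#' @export
tabulateVariants <- function(bins) {
  if (!nrow(bins)) stop("no binned reads to tabulate")
  amp <- paste(bins$specimen, bins$marker, sep = ":")
  key <- paste(bins$marker, bins$core, sep = "|")
  tab <- table(factor(key), factor(amp))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
    dimnames = dimnames(tab))
  vkey <- rownames(counts)
  vsplit <- regmatches(vkey, regexpr("\\|", vkey), invert = TRUE)
  marker <- vapply(vsplit, `[`, character(1), 1)
  seqs <- vapply(vsplit, `[`, character(1), 2)
  aname <- colnames(counts)
  asplit <- strsplit(aname, ":", fixed = TRUE)
  amps <- data.frame(
    amplicon_id = aname,
    specimen = vapply(asplit, `[`, character(1), 1),
    marker = vapply(asplit, `[`, character(1), 2),
    n_reads = colSums(counts),
    stringsAsFactors = FALSE
  )
  rownames(amps) <- NULL
  freqs <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  variants <- data.frame(
    variant_id = sprintf("V%05d", seq_along(vkey)),
    marker = marker,
    sequence = seqs,
    mpaf = apply(freqs, 1, max),
    n_amplicons = rowSums(counts > 0),
    status = "unresolved",
    stringsAsFactors = FALSE
  )
  dimnames(counts) <- list(variants$variant_id, amps$amplicon_id)
  new("VariantTable", variants = variants, counts = counts, amplicons = amps)
}

#' Collapse rare error variants into abundant parents
#'
#' Count-based correction in the spirit of amplicon-denoising pipelines:
#' variants are processed in increasing order of total read count, and a
#' variant is merged into the most similar variant of the same marker and
#' length whose total count is at least `1/merge_ratio` times larger,
#' provided the Hamming distance does not exceed `max_dist`. Point-error
#' reads (each erroneous sequence is individually rare) are thereby folded
#' back into their template; distinct true alleles, whose counts are of the
#' same order, are never merged into one another.
#'
#' @param vt a [VariantTable-class].
#' @param max_dist maximum Hamming distance for a merge (default 8).
#' @param merge_ratio maximum child/parent total-count ratio (default 0.1).
#' @return A new, smaller [VariantTable-class].
#' @export
denoiseVariants <- function(vt, max_dist = 8, merge_ratio = 0.1) {
  v <- variantInfo(vt)
  counts <- variantCounts(vt)
  keep_rows <- rep(TRUE, nrow(v))
  for (mk in unique(v$marker)) {
    for (L in unique(nchar(v$sequence[v$marker == mk]))) {
      idx <- which(v$marker == mk & nchar(v$sequence) == L)
      if (length(idx) < 2) next
      tot <- rowSums(counts[idx, , drop = FALSE])
      ord <- idx[order(tot)]
      enc <- .char_int(v$sequence[ord])
      onehot <- lapply(1:4, function(b) (enc == b) * 1)
      totv <- setNames(rowSums(counts[ord, , drop = FALSE]), NULL)
      for (k in seq_along(ord)) {
        cand <- which(totv >= totv[k] / merge_ratio & seq_along(ord) != k)
        if (!length(cand)) next
        matches <- numeric(length(cand))
        for (b in 1:4) {
          matches <- matches +
            as.numeric(onehot[[b]][cand, , drop = FALSE] %*% onehot[[b]][k, ])
        }
        d <- L - matches
        j <- cand[which.min(d)]
        if (min(d) <= max_dist) {
          counts[ord[j], ] <- counts[ord[j], ] + counts[ord[k], ]
          totv[j] <- totv[j] + totv[k]
          counts[ord[k], ] <- 0L
          totv[k] <- 0L
          keep_rows[ord[k]] <- FALSE
        }
      }
    }
  }
  counts <- counts[keep_rows, , drop = FALSE]
  v <- v[keep_rows, , drop = FALSE]
  freqs <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  v$mpaf <- apply(freqs, 1, max)
  v$n_amplicons <- rowSums(counts > 0)
  rownames(v) <- NULL
  amps <- ampliconInfo(vt)
  amps$n_reads <- colSums(counts)
  new("VariantTable", variants = v, counts = counts, amplicons = amps)
}

.first_mismatch <- function(a, b) {
  d <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(d)) c(Inf, -Inf) else c(min(d), max(d))
}

# Is variant v explainable, within one amplicon, as a 1-bp substitution
# from, or a single-crossover recombinant of, strictly higher-frequency
# variants? Returns "substitution", "chimera" or NA.
.explain_variant <- function(vseq, parent_seqs) {
  parent_seqs <- parent_seqs[nchar(parent_seqs) == nchar(vseq)]
  if (!length(parent_seqs)) return(NA_character_)
  fl <- vapply(parent_seqs, function(p) .first_mismatch(vseq, p), numeric(2))
  nd <- vapply(parent_seqs, function(p) hammingDistance(vseq, p), numeric(1))
  if (any(nd == 1)) return("substitution")
  L <- nchar(vseq)
  if (length(parent_seqs) >= 2) {
    for (a in seq_along(parent_seqs)) {
      for (b in seq_along(parent_seqs)) {
        if (a == b) next
        # v = prefix(parent a) + suffix(parent b), crossover internal
        if (fl[2, b] < fl[1, a] && fl[1, a] >= 2 && fl[2, b] <= L - 1)
          return("chimera")
      }
    }
  }
  NA_character_
}

#' Classify variants and call true alleles
#'
#' Applies the validation rules in fixed order to every variant:
#' (1) a length offset from the reference frame that is not a multiple of 3
#' is a frameshift indel -> `excluded_frameshift`; (2) a variant with MPAF
#' below `mpaf_artefact_threshold` that is explainable as a single
#' substitution from, or single-crossover recombinant of, strictly
#' higher-frequency variants co-occurring in one of its amplicons ->
#' `artefact_substitution` / `artefact_chimera`; (3) an amplicon frequency
#' at or above `auto_accept_threshold` is never explainable by artefacts ->
#' `true_allele`; (4) below that level, a singleton (present in a single
#' amplicon across all data sets) is `excluded_singleton` unless its MPAF
#' reaches the singleton-policy floor; (5) any other variant with MPAF at
#' or above the artefact threshold -> `true_allele`. Anything left is
#' `unresolved`.
#'
#' Artefact explanations are sought in every amplicon in which the variant
#' occurs; the variant is an artefact only if each occurrence is explainable
#' ("higher-frequency" means strictly greater within-amplicon frequency;
#' ties are not explainable).
#'
#' @param vt a [VariantTable-class] (after optional [denoiseVariants()]).
#' @param mpaf_artefact_threshold MPAF below which artefact explanations are
#'   sought (default 0.05).
#' @param auto_accept_threshold within-amplicon frequency that cannot be an
#'   artefact (default 0.50).
#' @param singleton_policy list with `accept_mpaf`: singleton variants with
#'   MPAF at or above this floor are retained as true alleles
#'   (default 0.20).
#' @param exon2_length reference frame length for frameshift detection.
#' @return The [VariantTable-class] with final `status` per variant.
#' @export
classifyAndCall <- function(vt, mpaf_artefact_threshold = 0.05,
                            auto_accept_threshold = 0.50,
                            singleton_policy = list(accept_mpaf = 0.20),
                            exon2_length = 276) {
  v <- variantInfo(vt)
  counts <- variantCounts(vt)
  freqs <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  status <- rep("unresolved", nrow(v))

  frameshift <- (nchar(v$sequence) - exon2_length) %% 3 != 0
  status[frameshift] <- "excluded_frameshift"

  explain <- rep(NA_character_, nrow(v))
  low <- which(!frameshift & v$mpaf < mpaf_artefact_threshold)
  for (i in low) {
    kinds <- character(0)
    amps_i <- which(counts[i, ] > 0)
    for (a in amps_i) {
      parents <- which(freqs[, a] > freqs[i, a])
      kind <- .explain_variant(v$sequence[i], v$sequence[parents])
      if (is.na(kind)) {
        kinds <- character(0)
        break
      }
      kinds <- c(kinds, kind)
    }
    if (length(kinds)) {
      explain[i] <- if (any(kinds == "chimera") && all(kinds != "substitution"))
        "chimera" else if (all(kinds == "substitution")) "substitution"
      else "chimera"
    }
  }
  is_artefact <- !frameshift & v$mpaf < mpaf_artefact_threshold & !is.na(explain)
  status[is_artefact & explain == "substitution"] <- "artefact_substitution"
  status[is_artefact & explain == "chimera"] <- "artefact_chimera"

  open <- !frameshift & !is_artefact
  status[open & v$mpaf >= auto_accept_threshold] <- "true_allele"

  # singleton gate: below the auto-accept level, a variant seen in a single
  # amplicon across all data sets needs the singleton-policy MPAF floor
  singleton <- status == "unresolved" & open & v$n_amplicons == 1
  floor_ok <- v$mpaf >= singleton_policy$accept_mpaf
  status[singleton & floor_ok] <- "true_allele"
  status[singleton & !floor_ok] <- "excluded_singleton"

  accept <- status == "unresolved" & open & v$mpaf >= mpaf_artefact_threshold
  status[accept] <- "true_allele"

  v$status <- status
  new("VariantTable", variants = v, counts = counts,
    amplicons = ampliconInfo(vt))
}

#' Per-specimen allele calls from a classified variant table
#'
#' A true-allele variant is called in a specimen when its within-amplicon
#' frequency there is at least `call_min`. Per specimen, at most 4 alleles
#' per lineage are retained (the strongest by frequency), enforcing the
#' two-duplicated-diploid-loci cap of 8 alleles in total.
#'
#' @param vt classified [VariantTable-class].
#' @param call_min minimum within-amplicon frequency for a presence call
#'   (default 0.05).
#' @return data.frame with columns `specimen`, `marker`, `variant_id`,
#'   `sequence`, `freq`.
#' @export
callGenotypes <- function(vt, call_min = 0.05) {
  v <- variantInfo(vt)
  counts <- variantCounts(vt)
  amps <- ampliconInfo(vt)
  freqs <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  rows <- list()
  true_idx <- which(v$status == "true_allele")
  for (a in seq_len(ncol(counts))) {
    pres <- true_idx[freqs[true_idx, a] >= call_min]
    if (!length(pres)) next
    ord <- pres[order(-freqs[pres, a])]
    ord <- head(ord, 4L)  # per-lineage cap (one amplicon = one marker)
    rows[[length(rows) + 1]] <- data.frame(
      specimen = amps$specimen[a], marker = amps$marker[a],
      variant_id = v$variant_id[ord], sequence = v$sequence[ord],
      freq = freqs[ord, a], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(specimen = character(), marker = character(),
      variant_id = character(), sequence = character(), freq = numeric())
  rownames(out) <- NULL
  out
}

#' Assign species-aware nomenclature to validated alleles
#'
#' Alleles found only in species A are `Pato-`, only in species B `Chna-`,
#' and alleles shared by both species or found solely in hybrids `Pctn-`.
#' Names have the form `<prefix>-DAB<lineage>*NN` with NN sequential per
#' lineage, ordered by decreasing number of carrier specimens (ties by
#' sequence), so names are stable across reruns of an identical catalog.
#'
#' @param calls data.frame from [callGenotypes()].
#' @param specimen_meta data.frame with `specimen`, `species`
#'   (A, B or hybrid) and optionally `population`.
#' @return An [AlleleCatalog-class]; the table maps `variant_id` to `name`,
#'   `lineage` and the occurrence set.
#' @export
assignNomenclature <- function(calls, specimen_meta) {
  if (!nrow(calls)) stop("naming error: no validated alleles to name")
  sp <- setNames(specimen_meta$species, specimen_meta$specimen)
  occ <- tapply(sp[calls$specimen], calls$variant_id, function(x)
    paste(sort(unique(x)), collapse = ","))
  nspec <- tapply(calls$specimen, calls$variant_id, function(x)
    length(unique(x)))
  vinfo <- unique(calls[, c("variant_id", "marker", "sequence")])
  vinfo$occurrence <- unname(occ[vinfo$variant_id])
  vinfo$n_specimens <- unname(nspec[vinfo$variant_id])
  if (any(is.na(vinfo$occurrence) | vinfo$occurrence == ""))
    stop("naming error: allele with empty occurrence set")
  has <- function(o, s) vapply(strsplit(o, ","), function(x) s %in% x,
    logical(1))
  inA <- has(vinfo$occurrence, "A")
  inB <- has(vinfo$occurrence, "B")
  prefix <- ifelse(inA & !inB, "Pato", ifelse(inB & !inA, "Chna", "Pctn"))
  vinfo$prefix <- prefix
  vinfo$lineage <- vinfo$marker
  tb <- vinfo[order(vinfo$lineage, -vinfo$n_specimens, vinfo$sequence), ]
  tb$name <- NA_character_
  for (l in unique(tb$lineage)) {
    idx <- which(tb$lineage == l)
    dig <- sub("DAB", "", l)
    tb$name[idx] <- sprintf("%s-DAB%s*%02d", tb$prefix[idx], dig,
      seq_along(idx))
  }
  rownames(tb) <- NULL
  new("AlleleCatalog", table = tb[, c("name", "variant_id", "sequence",
    "lineage", "occurrence", "n_specimens")])
}

#' Build the specimen x allele presence/absence matrix
#'
#' Each validated allele is one dominant binary locus; row sums equal
#' per-specimen allele counts. Specimens without any validated allele get
#' an all-zero row (retained with a warning).
#'
#' @param calls data.frame from [callGenotypes()].
#' @param catalog an [AlleleCatalog-class] (columns used to order/name
#'   alleles); optional.
#' @param specimen_meta data.frame with `specimen` and `population`.
#' @return A [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(calls, catalog = NULL, specimen_meta) {
  specs <- specimen_meta$specimen
  if (!is.null(catalog)) {
    tb <- catalogTable(catalog)
    aid <- tb$variant_id
    anames <- tb$name
  } else {
    aid <- sort(unique(calls$variant_id))
    anames <- aid
  }
  m <- matrix(0L, length(specs), length(aid),
    dimnames = list(specs, anames))
  ri <- match(calls$specimen, specs)
  ci <- match(calls$variant_id, aid)
  ok <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[ok], ci[ok])] <- 1L
  if (any(rowSums(m) == 0))
    warning(sum(rowSums(m) == 0), " specimen(s) without validated alleles",
      " (all-zero rows retained)")
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  new("PresenceMatrix", presence = m,
    population = specimen_meta$population[match(specs,
      specimen_meta$specimen)])
}

#' Per-population allele summary
#'
#' One row per group: total distinct alleles, private alleles (observed in
#' that group only), per-lineage allele counts, and the per-specimen allele
#' count distribution (min-max, mean, SD), mirroring a population summary
#' table. Also returns per-lineage expression-pattern frequencies (0, 1 or
#' >= 2 alleles of each lineage per specimen).
#'
#' @param pm a [PresenceMatrix-class].
#' @param catalog an [AlleleCatalog-class] (for lineage lookup).
#' @param grouping optional grouping vector (default: the populations).
#' @return list with `summary` (data.frame) and `patterns` (per-group
#'   lineage expression pattern frequency tables).
#' @export
summarizePopulation <- function(pm, catalog, grouping = NULL) {
  m <- presence(pm)
  if (is.null(grouping)) grouping <- populations(pm)
  stopifnot(length(grouping) == nrow(m))
  tb <- catalogTable(catalog)
  lin <- setNames(tb$lineage, tb$name)[colnames(m)]
  groups <- unique(grouping)
  present_in <- sapply(groups, function(g)
    colSums(m[grouping == g, , drop = FALSE]) > 0)
  rows <- list()
  patterns <- list()
  for (g in groups) {
    sub <- m[grouping == g, , drop = FALSE]
    n <- nrow(sub)
    here <- colSums(sub) > 0
    if (n == 0) {
      rows[[g]] <- data.frame(group = g, n = 0, n_alleles = 0, private = 0,
        dab1 = 0, dab3 = 0, min = 0, max = 0, mean = 0, sd = 0)
      next
    }
    priv <- sum(here & rowSums(present_in[, groups != g, drop = FALSE]) == 0)
    per_spec <- rowSums(sub)
    rows[[g]] <- data.frame(
      group = g, n = n, n_alleles = sum(here), private = priv,
      dab1 = sum(here & lin == "DAB1"), dab3 = sum(here & lin == "DAB3"),
      min = min(per_spec), max = max(per_spec),
      mean = mean(per_spec), sd = if (n > 1) sd(per_spec) else 0,
      stringsAsFactors = FALSE)
    pat <- sapply(c("DAB1", "DAB3"), function(l) {
      cnt <- rowSums(sub[, lin == l, drop = FALSE])
      c(`0` = mean(cnt == 0), `1` = mean(cnt == 1), `2+` = mean(cnt >= 2))
    })
    patterns[[g]] <- pat
  }
  list(summary = do.call(rbind, rows), patterns = patterns)
}

#' End-to-end genotyping of a read set
#'
#' Convenience wrapper: demultiplex, bin and trim, tabulate, denoise,
#' classify, call, and name.
#'
#' @param reads named character vector of reads.
#' @param layout plate layout.
#' @param references per-marker interior references ([markerReferences()]).
#' @param specimen_meta data.frame `specimen`, `population`, `species`.
#' @param allow_mismatch tag mismatches tolerated (default 0).
#' @param denoise logical; collapse rare error variants first (default TRUE).
#' @param ... passed to [classifyAndCall()].
#' @return list with `variant_table`, `calls`, `catalog`, `presence`.
#' @export
genotypeReads <- function(reads, layout, references, specimen_meta,
                          allow_mismatch = 0, denoise = TRUE, ...) {
  dm <- demultiplexReads(reads, layout, allow_mismatch)
  bins <- binReads(reads, dm$assigned, references)
  vt <- tabulateVariants(bins)
  if (denoise) vt <- denoiseVariants(vt)
  vt <- classifyAndCall(vt, ...)
  calls <- callGenotypes(vt)
  catalog <- assignNomenclature(calls, specimen_meta)
  pmx <- buildPresenceMatrix(calls, catalog, specimen_meta)
  tbl <- catalogTable(catalog)
  calls$name <- tbl$name[match(calls$variant_id, tbl$variant_id)]
  list(variant_table = vt, calls = calls, catalog = catalog, presence = pmx)
}
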