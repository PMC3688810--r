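# End-to-end orchestration: simulate -> genotype -> phylo ->
# selection/geneconv -> popgen, with one structured config, per-stage TSV
# outputs and a JSON manifest recording seeds, thresholds and file digests.

#' Default pipeline configuration
#'
#' @return named list of all stage toggles, thresholds and sizes; values
#'   can be overridden via [runPipeline()]'s `config` argument.
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    stages = c("simulate", "genotype", "phylo", "selection", "geneconv",
      "popgen"),
    n_per_lineage = 8,
    n_specimens = 48,
    coverage = c(300, 800),
    error_rate = 0.005,
    chimera_fraction = 0.02,
    allow_mismatch = 0,
    mpaf_threshold = 0.05,
    accept_threshold = 0.50,
    min_identity = 0.80,
    nj_bootstrap = 200,
    ng_bootstrap = 1000,
    geneconv_perms = 1000,
    fit_site_models = FALSE,
    fst_bootstrap = 2000,
    msat_loci = 25,
    msat_F = 0.2,
    admixture_reps = 1500,
    admixture_burnin = 500,
    fst_min_n = 5
  )
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$mpaf_threshold > 0, cfg$mpaf_threshold < 1,
    cfg$accept_threshold >= cfg$mpaf_threshold, cfg$accept_threshold <= 1,
    cfg$min_identity > 0, cfg$min_identity <= 1,
    cfg$coverage[1] >= 1)
  invisible(cfg)
}

.writeTsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort
#' and writes every stage output (TSV/FASTA/Newick) plus a JSON manifest to
#' `out_dir`. A downstream stage whose upstream output is missing raises a
#' dependency error naming the stage.
#'
#' @param out_dir output directory (created if absent).
#' @param config named list overriding entries of [defaultConfig()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(out_dir, config = list()) {
  cfg <- modifyList(defaultConfig(), config)
  .validateConfig(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- function(s) s %in% cfg$stages
  res <- list(config = cfg)
  need <- function(s, what) {
    if (is.null(res[[what]]))
      stop("dependency error: stage '", s, "' requires '", what, "'")
  }

  if (on("simulate")) {
    pool <- generateAllelePool(cfg$n_per_lineage, seed = cfg$seed)
    geno <- simulateGenotypes(pool, cfg$n_specimens, seed = cfg$seed + 1)
    tags <- selectTagSet(enumerateCandidateTags(7), target_size = 40,
      seed = cfg$seed)
    layout <- buildPlateLayout(tags, specimens = geno$specimen)
    sim <- simulateReadSet(geno, pool, layout, coverage = cfg$coverage,
      error_rate = cfg$error_rate,
      chimera_fraction = cfg$chimera_fraction, seed = cfg$seed + 2)
    msat <- simulateMicrosatPanel(cfg$msat_loci,
      n_per_pop = c(ceiling(cfg$n_specimens / 2),
        floor(cfg$n_specimens / 2)),
      F = cfg$msat_F, seed = cfg$seed + 3)
    res$pool <- pool
    res$genotypes <- geno
    res$layout <- layout
    res$sim <- sim
    res$msat <- msat
    writeFasta(alleleSequences(pool), file.path(out_dir, "allele_pool.fasta"))
    writeReadsFastq(sim$reads, file.path(out_dir, "reads.fastq"))
    .writeTsv(sim$truth, out_dir, "truth.tsv")
    .writeTsv(geno, out_dir, "genotypes_true.tsv")
    writePlateLayout(layout, file.path(out_dir, "plate_layout.csv"))
    .writeTsv(msat$genotypes, out_dir, "microsat.tsv")
  }

  if (on("genotype")) {
    need("genotype", "sim")
    meta <- res$genotypes[, c("specimen", "population", "species")]
    gt <- genotypeReads(res$sim$reads, res$layout,
      markerReferences(res$pool), meta,
      allow_mismatch = cfg$allow_mismatch,
      mpaf_artefact_threshold = cfg$mpaf_threshold,
      auto_accept_threshold = cfg$accept_threshold)
    res$genotyping <- gt
    v <- variantInfo(gt$variant_table)
    .writeTsv(v, out_dir, "variant_table.tsv")
    .writeTsv(gt$calls, out_dir, "allele_calls.tsv")
    .writeTsv(catalogTable(gt$catalog), out_dir, "allele_catalog.tsv")
    pmx <- gt$presence
    .writeTsv(data.frame(specimen = rownames(presence(pmx)),
      population = populations(pmx), presence(pmx),
      check.names = FALSE), out_dir, "presence_matrix.tsv")
    tb <- catalogTable(gt$catalog)
    writeFasta(setNames(tb$sequence, tb$name),
      file.path(out_dir, "validated_alleles.fasta"))
  }

  if (on("phylo")) {
    need("phylo", "genotyping")
    tb <- catalogTable(res$genotyping$catalog)
    seqs <- setNames(tb$sequence, tb$name)
    tr <- bootstrapSupport(seqs, replicates = cfg$nj_bootstrap,
      seed = cfg$seed + 4)
    res$tree <- tr
    ape::write.tree(tr, file.path(out_dir, "nj_tree.nwk"))
  }

  if (on("selection")) {
    need("selection", "genotyping")
    tb <- catalogTable(res$genotyping$catalog)
    seqs <- setNames(tb$sequence, tb$name)
    mask <- defaultAbsMask(nchar(seqs[1]) / 3)
    aln <- codonAlignment(seqs, mask)
    ng <- lapply(c("all", "ABS", "nonABS"), function(p)
      partitionRates(aln, p, bootstrap_reps = cfg$ng_bootstrap,
        seed = cfg$seed + 5))
    ng_df <- do.call(rbind, lapply(ng, function(x)
      data.frame(partition = x$partition, n_codons = x$n_codons,
        dN = x$dN, SE_dN = x$SE_dN, dS = x$dS, SE_dS = x$SE_dS,
        Z = x$Z, p = x$p)))
    res$ng <- ng_df
    .writeTsv(ng_df, out_dir, "ng86_partitions.tsv")
    if (isTRUE(cfg$fit_site_models)) {
      need("selection site models", "tree")
      fits <- list()
      f0 <- fitSiteModel(aln, res$tree, "M0")
      sc <- modelParams(f0)$scale
      fits$M0 <- f0
      for (mdl in c("M1a", "M2a", "M3", "M7", "M8")) {
        fits[[mdl]] <- fitSiteModel(aln, res$tree, mdl, scale = sc,
          nstarts = 2)
      }
      fit_df <- do.call(rbind, lapply(fits, function(f) data.frame(
        model = f@model, npar = f@npar, lnL = f@logLik,
        params = paste(names(f@params)[!vapply(f@params, is.numeric,
          logical(1)) | lengths(f@params) == 1],
          signif(unlist(f@params[lengths(f@params) == 1]), 4),
          sep = "=", collapse = ", "))))
      res$site_fits <- fits
      .writeTsv(fit_df, out_dir, "site_models.tsv")
      beb <- bebSitePosteriors(fits$M8, aln, res$tree)
      .writeTsv(beb$sites, out_dir, "beb_sites.tsv")
      res$beb <- beb
    }
  }

  if (on("geneconv")) {
    need("geneconv", "genotyping")
    tb <- catalogTable(res$genotyping$catalog)
    seqs <- setNames(tb$sequence, tb$name)
    gc <- geneconvScan(seqs, n_perm = cfg$geneconv_perms,
      seed = cfg$seed + 6)
    res$geneconv <- gc
    if (!is.null(gc$inner) && nrow(gc$inner))
      .writeTsv(head(gc$inner, 50), out_dir, "geneconv_inner.tsv")
    if (!is.null(gc$outer) && nrow(gc$outer))
      .writeTsv(head(gc$outer, 50), out_dir, "geneconv_outer.tsv")
  }

  if (on("popgen")) {
    need("popgen", "genotyping")
    need("popgen", "msat")
    pmx <- res$genotyping$presence
    fst_b <- fstBinary(pmx, bootstrap_reps = cfg$fst_bootstrap,
      min_n = cfg$fst_min_n, seed = cfg$seed + 7)
    fst_h <- fstHaplotype(pmx, min_n = cfg$fst_min_n)
    if (!is.null(fst_b)) .writeTsv(fst_b, out_dir, "fst_binary.tsv")
    if (!is.null(fst_h)) .writeTsv(fst_h, out_dir, "fst_haplotype.tsv")
    res$fst_binary <- fst_b
    res$fst_haplotype <- fst_h
    ms <- microsatArray(res$msat$genotypes)
    adm <- admixtureInfer(ms$geno, K = 2, reps = cfg$admixture_reps,
      burn_in = cfg$admixture_burnin, seed = cfg$seed + 8)
    res$admixture <- adm
    .writeTsv(data.frame(ind = rownames(ms$geno), pop = ms$pop, adm$Q),
      out_dir, "admixture_q.tsv")
    div <- diversityAndCorrelation(pmx)
    .writeTsv(div$table, out_dir, "diversity.tsv")
    res$diversity <- div
  }

  manifest <- list(
    package = "ampliMHC",
    version = as.character(utils::packageVersion("ampliMHC")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = cfg$seed,
    stages = cfg$stages,
    thresholds = cfg[c("mpaf_threshold", "accept_threshold",
      "min_identity")],
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE)))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Render a plain-text report from a run directory
#'
#' Reads only the stage TSVs (no recomputation) and renders population
#' summary, dN/dS and model-fit sections; missing stages are reported as
#' explicit gaps. Regeneration is idempotent.
#'
#' @param run_dir a directory produced by [runPipeline()].
#' @param file output file (default `report.txt` inside `run_dir`).
#' @return the report path, invisibly.
#' @export
generateReport <- function(run_dir, file = file.path(run_dir, "report.txt")) {
  if (!dir.exists(run_dir) ||
      !file.exists(file.path(run_dir, "manifest.json")))
    stop("not a completed run directory: ", run_dir)
  man <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  lines <- c("ampliMHC pipeline report",
    paste0("run date: ", man$date, "; seed: ", man$seed), "")
  grab <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) return(NULL)
    tryCatch(read.delim(p, check.names = FALSE), error = function(e) NULL)
  }
  pres <- grab("presence_matrix.tsv")
  cat_tb <- grab("allele_catalog.tsv")
  if (!is.null(pres) && !is.null(cat_tb)) {
    m <- as.matrix(pres[, -(1:2), drop = FALSE])
    pops <- pres$population
    lines <- c(lines, "Per-population allele summary", "group\tn\talleles\tper-specimen (min-max, mean, sd)")
    for (g in unique(pops)) {
      sub <- m[pops == g, , drop = FALSE]
      per <- rowSums(sub)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d-%d (%.2f, %.2f)", g,
        nrow(sub), sum(colSums(sub) > 0), min(per), max(per), mean(per),
        sd(per)))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "[genotyping outputs missing]", "")
  }
  ng <- grab("ng86_partitions.tsv")
  if (!is.null(ng)) {
    lines <- c(lines, "dN/dS by partition (NG86 + JC, bootstrap SE)",
      "partition\tdN (SE)\tdS (SE)\tZ\tp")
    for (i in seq_len(nrow(ng))) {
      lines <- c(lines, sprintf("%s\t%.3f (%.3f)\t%.3f (%.3f)\t%.3f\t%.3f",
        ng$partition[i], ng$dN[i], ng$SE_dN[i], ng$dS[i], ng$SE_dS[i],
        ng$Z[i], ng$p[i]))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "[selection outputs missing]", "")
  }
  sm <- grab("site_models.tsv")
  if (!is.null(sm)) {
    lines <- c(lines, "Codon site models",
      apply(sm, 1, function(r) paste(r, collapse = "\t")), "")
  }
  fst <- grab("fst_binary.tsv")
  if (!is.null(fst)) {
    lines <- c(lines, "Pairwise F_ST (binary encoded MHC)",
      "pop1\tpop2\tFst [95% CI]")
    for (i in seq_len(nrow(fst))) {
      lines <- c(lines, sprintf("%s\t%s\t%.3f [%.3f, %.3f]", fst$pop1[i],
        fst$pop2[i], fst$fst[i], fst$ci_lo[i], fst$ci_hi[i]))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Default antigen-binding-site mask
#'
#' The ABS codons of the beta-1 domain inferred from the human DRB1 crystal
#' structure, mapped onto an exon-2 codon alignment by a configurable
#' offset. The mapping onto any particular alignment is an explicit input:
#' this helper returns the bundled DRB1 beta-1 positions shifted by
#' `offset` and clipped to `ncodon`.
#'
#' @param ncodon number of codons in the target alignment.
#' @param offset shift applied to the DRB1 positions (default 0).
#' @return integer vector of 1-based codon indices.
#' @export
defaultAbsMask <- function(ncodon, offset = 0) {
  path <- system.file("extdata", "abs_mask_drb1_beta1.txt",
    package = "ampliMHC")
  ln <- grep("^[0-9]+$", trimws(readLines(path)), value = TRUE)
  pos <- as.integer(ln) + offset
  sort(unique(pos[pos >= 1 & pos <= ncodon]))
}
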