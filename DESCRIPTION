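Package: ampliMHC
Title: Amplicon Genotyping and Evolutionary Analysis of Cyprinid MHC IIB (DAB) Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tag-based multiplex amplicon genotyping of duplicated
    MHC class IIB (DAB) exon-2 loci in cyprinid fish, and for downstream
    evolutionary analysis of the validated alleles. Includes design of 7-bp
    multiplexing tags and 96-well plate layouts, read demultiplexing,
    per-amplicon variant tabulation with maximum per-amplicon frequency
    (MPAF) based allele validation and artefact (substitution/chimera)
    classification, allele nomenclature, neighbour-joining phylogenies with
    bootstrap, Nei-Gojobori dN/dS with partition Z-tests, maximum-likelihood
    codon site models (M0, M1a, M2a, M3, M7, M8) with likelihood-ratio tests
    and Bayes empirical Bayes identification of positively selected sites,
    gene-conversion fragment detection with permutation significance, and
    presence/absence population genetics (dominant-marker F_ST, Bayesian
    admixture clustering with Evanno's Delta-K, Mantel and Spearman tests).
    A synthetic-data generator produces tagged reads, genotypes and
    microsatellite panels with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    jsonlite,
    vegan,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
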