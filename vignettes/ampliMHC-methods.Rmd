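---
title: "Methods: amplicon genotyping and evolutionary analysis of duplicated MHC IIB genes"
author: "ampliMHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon genotyping and evolutionary analysis of duplicated MHC IIB genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind each stage of the
package, the assumptions they rest on, the tunable parameters with their
defaults, and the numerical choices made where the design was genuinely
open. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The biological setting

Cyprinid MHC class IIB (*DAB*) genes occur as two deeply divergent allelic
lineages, *DAB1*-like and *DAB3*-like, interpreted as duplicated loci each
of which may itself be duplicated. A diploid fish can therefore carry up
to 4 alleles per lineage and 8 in total, and alleles can only be scored as
present or absent in an individual — there is no locus assignment, so each
allele behaves as a dominant binary marker in population analyses. Exon 2
(276 bp, 92 codons) encodes the β1 domain containing the peptide-binding
region and carries nearly all the polymorphism.

## Tag design

Multiplexing tags are 7-mers over {A,C,G,T} constrained to contain

* no homopolymer — interpreted strictly as *no two identical adjacent
  bases*, because pyrosequencing chemistry is homopolymer-error-prone;
* no tandem motif repeat — no immediate repeat of any motif of length ≥ 2
  anywhere in the tag (e.g. `ACAC`, `TGGTGG`); this is the strictest
  defensible reading of "no motif repetition" and both predicates are
  switchable in `enumerateCandidateTags()`;
* pairwise Hamming distance ≥ 3 across the selected set, so that any
  single sequencing error still leaves a read closer to its true tag than
  to any other.

Selection is greedy accretion over the lexicographic candidate list with
seeded random restarts. The required code size (≥ 40 tags at distance 3
in a length-7 quaternary space) is far below coding-theory limits, so the
greedy construction always succeeds; optimal (maximum) code construction
is deliberately out of scope. `buildPlateLayout()` arranges 12
forward-tagged and 8 reverse-tagged primers row × column on a 96-well
plate, giving each specimen a unique ordered tag pair.

Primer coordinates use the convention that an "annealing position" is the
1-based plus-strand coordinate of the 5'-most base of the primer's binding
site; under that convention the published primer positions reproduce the
210-marker product arithmetic exactly (`ampliconLength()`): 342 bp and
350 bp untagged, 356 bp and 364 bp with 7-bp tags on both primers.

## Synthetic data generator

The generator defines the study conditions under which every guarantee of
the pipeline is tested. It emulates:

* an allele pool of two lineages descending from founders separated by
  0.20 substitutions/site (between-lineage), alleles within a lineage at
  0.03 from their founder — values chosen once to mirror the deep
  *DAB1*/*DAB3* split versus shallow within-lineage variation; pools are
  regenerated (bounded retries) until the minimum between-lineage distance
  exceeds the maximum within-lineage distance, and all sequences are
  stop-free in frame 0;
* species assignment of alleles (A-only / B-only / shared at
  0.4/0.3/0.3), with at least one shared allele per lineage whenever
  n ≥ 3;
* per-specimen genotypes drawn from species-specific expression-pattern
  weights over per-lineage allele counts. The defaults encode the
  study system's pattern: the native species mostly expresses only the
  DAB3 lineage with ~2 alleles per fish, the invasive species expresses
  both lineages with ~3, hybrids are intermediate. Caps of ≤ 4 per
  lineage and ≤ 8 total are enforced structurally;
* reads of the exact tagged-amplicon structure
  `Ftag + Fprimer + template + revcomp(Rprimer) + revcomp(Rtag)`, the
  template being the exon-2 core padded with conserved exon-1/exon-3
  flanks so the interior product lengths (303/312 bp) match the marker
  arithmetic. Per-amplicon coverage is uniform on c(300, 2000) by default
  ("hundreds to thousands"); allele shares within an amplicon are equal
  unless a Dirichlet concentration is supplied;
* artefacts: uniform per-base point errors (default 0.005 — the paper
  does not state its realized error rate; this is a realistic
  pyrosequencing point-error figure) applied over the whole read
  including tags, and chimeras formed by a single uniform crossover
  between two distinct templates *of the same amplicon* (default fraction
  0.02). Homopolymer indel spectra and quality-aware calling are
  non-goals; quality strings are constant.
* microsatellite panels under a Balding–Nichols model: ancestral per-locus
  frequencies are Dirichlet(1), population frequencies
  Dirichlet(p·(1−F)/F), so the expected Wright F~ST~ equals `F`; hybrids
  draw each allele copy from population 1 with their admixture
  proportion.

Every read is listed exactly once in a truth table (source allele, chimera
parents and breakpoint, error count, tag-mutation flag), which is what the
genotyping guarantees are scored against. What passing tests on this
generator do **not** show: robustness to 454 homopolymer indels, to
unequal pooling beyond the Dirichlet option, to primer-binding variation,
or to contamination between plates.

## Genotyping and MPAF validation

Demultiplexing matches both 7-bp tags within a configurable Hamming
tolerance (default 0: with design distance 3, a 1-mismatch tolerance is
safe, but the default drops tag-mutated reads instead). Ambiguous matches
go to the unassigned pool with a reason. Tags and primers are then
stripped by exact coordinates (their lengths are known), the marker is
recognized from the forward primer (≤ 3 mismatches) and confirmed by
ungapped identity ≥ 0.80 against per-marker references — the identity
threshold replaces a BLAST e-value cutoff; for two lineages this deeply
split the two criteria discriminate equivalently, and the threshold is a
parameter.

Tabulation counts each distinct trimmed core sequence per amplicon
(specimen × marker) and computes the **MPAF**, the variant's maximum
within-amplicon frequency across all amplicons.

Before classification, `denoiseVariants()` collapses rare point-error
variants into abundant parents: variants are processed in increasing count
order and merged into the most similar same-length variant at least
10× more abundant, within Hamming distance 8. The rationale is
arithmetic: at a 1% per-base error rate over 276 bp only
`0.99^276 ≈ 6%` of a template's reads are error-free, so the *exact* true
sequence would sit below any frequency threshold, while each individual
erroneous sequence is nearly unique. Count-ratio merging restores the
template's support without ever merging two true alleles, whose counts
are of the same order (the 10× guard). This plays the role the original
workflow delegated to its amplicon-correction step and both knobs are
exposed.

Classification applies ordered rules: (1) length offsets that are not a
multiple of 3 are frameshift indels → excluded; (2) a variant with MPAF
< 5% explainable in *every* amplicon where it occurs as a 1-bp
substitution from, or a single-crossover recombinant of, strictly
higher-frequency variants of the same amplicon is an artefact (ties in
frequency do not explain); (3) a within-amplicon frequency ≥ 50% is never
an artefact → true allele; (4) below that, a singleton — a variant seen in
one amplicon across all data sets — is excluded unless its MPAF reaches
the singleton floor (default 0.20, motivated by replicate-PCR-confirmed
singletons being high-MPAF variants); (5) any other variant with MPAF
≥ 5% is a true allele. The singleton gate is placed *before* the ordinary
≥ 5% acceptance: placing it after (as a literal reading of the rule list
would have it) makes the singleton floor unreachable, since every variant
above 5% would already be accepted. `classifyAndCall()` is idempotent.

Validated alleles are named `<prefix>-DAB<lineage>*NN` with the prefix
determined by species occurrence (A-only → `Pato`, B-only → `Chna`,
shared or hybrid-only → `Pctn`) and NN sequential per lineage ordered by
carrier count then sequence, so names are stable across reruns.

## Phylogeny

Distances are p-distances or Jukes–Cantor
(d = −(3/4)·ln(1 − (4/3)p); pairs with p ≥ 0.75 raise a saturation
error), trees are neighbour-joining (via `ape`), negative branch-length
estimates are clamped to zero and flagged, and bootstrap support is the
percentage of column-resampled replicate trees containing each
bipartition, with supports > 50% shown by default. The distance model the
original analysis used is unstated; JC is the default with a p-distance
flag. The NJ topology also serves as the fixed tree for codon-model
fitting — a deliberate replacement of a heuristic ML tree search, since
site-model inference is robust to minor topology differences at this
divergence depth.

## NG86 dN/dS and the Z-test

`ng86Pairwise()` counts potential synonymous/nonsynonymous sites per codon
(each position contributes the fraction of its three possible changes that
are synonymous; changes to stop codons count as nonsynonymous) and
averages observed differences in multi-hit codons over all minimal
mutational pathways, excluding pathways through stop codons (all-blocked
codons fall back to all pathways). Proportions are Jukes–Cantor corrected.
The test suite checks the implementation against an independent
exhaustive-pathway oracle on every codon pair.

`partitionRates()` averages pairwise dN and dS over all sequence pairs
restricted to a codon partition — all codons, the ABS mask, or its
complement — with standard errors from a 1000-replicate codon-resampling
bootstrap. The ABS mask is an explicit input: the bundled file
`inst/extdata/abs_mask_drb1_beta1.txt` lists the β1-domain antigen-binding
positions from the human DRB1 crystal structure, mapped onto a target
alignment by a configurable offset (`defaultAbsMask()`), because the exact
mapping onto any particular exon-2 alignment is a choice the user must
own. The one-tailed Z-test uses Z = (dN − dS)/SE(dN − dS) with the
bootstrap SE of the difference; when Z ≤ 0 the p-value is reported as 1,
matching the reporting convention of the standard dN/dS software this
mirrors.

## Codon site models

The substitution process is a 61-state codon model: rate π~j~·κ^[ts]^·ω^[ns]^
for single-nucleotide codon changes, zero otherwise, with empirical F3x4
codon frequencies by default (equal-frequency option available).
Site-class mixtures follow the standard model menu — M0 (one ω), M1a
(ω~0~ < 1, ω = 1), M2a (adds ω~2~ > 1), M3 (three free classes), M7
(10-category discretized Beta(p, q)), M8 (Beta plus a free ω~s~ ≥ 1 class)
— with likelihoods computed by Felsenstein pruning over the fixed NJ
topology (Rcpp/Armadillo core, symmetric eigendecomposition of the
reversible rate matrix, per-node rescaling). Class rate matrices share a
common clock normalized so the *mixture-average* rate is one substitution
per codon per unit branch length, so high-ω classes evolve faster — the
standard convention, and essential for power.

Branch lengths: the NJ tree's relative branch lengths are retained and a
single scale factor (substitutions/codon) is optimized under M0, then
fixed for the richer models. Full per-branch optimization (≈ 80
parameters at a 40-allele scale) is not attempted; the scale-factor
narrowing of the "optimize under M0, then fix" strategy keeps fits
desk-scale while leaving ω, κ and the class structure — the quantities of
interest — freely estimated. κ is re-estimated within each model.

Optimization is bounded quasi-Newton (L-BFGS-B) on natural parameters
with 3 jittered restarts by default (`nstarts`); proportions use a
stick-breaking parameterization to stay on the simplex. LRTs compare the
standard nested pairs with df 4 (M0 vs M3) and 2 (M1a vs M2a, M7 vs M8),
the difference of free ω-structure parameter counts.

**BEB.** Posterior identification of positively selected sites integrates
over a discrete parameter grid with a uniform prior, holding κ,
frequencies and branch lengths at their MLEs (the empirical-Bayes
scheme). For M2a the grid is (p~0~, p~1~) on the simplex × 10 ω~0~
categories in (0,1) × 10 ω~2~ categories in (1,11). For M8: 10 p~0~
categories × a 10×10 log-spaced grid of beta shapes in [0.05, 5]
(log-spacing because MHC fits push both shapes well below 1) × 10 ω~s~
categories in (1,11); beta-class site likelihoods are linearly
interpolated in ω from a fixed 21-point grid on [0,1], which is accurate
because per-site likelihoods are smooth in ω. Sites with positive-class
posterior > 0.95 (and a > 0.99 tier) are reported as positively selected.

## Gene-conversion fragments

On the polymorphic columns of the alignment, an inner fragment for a
sequence pair is a maximal run of agreement bounded by discordant sites or
alignment ends; no mismatches are allowed within a fragment (the original
program's default scale) and the score is the number of polymorphic sites
spanned. Outer fragments are maximal runs of otherwise-monomorphic
columns at which one sequence differs from all the rest. Significance
permutes the order of polymorphic columns (site-order randomness null):
`sim_p` ranks an observed score against the permutation null of the
global maximum; the per-pair permutation p Bonferroni-scaled by the
number of pairs stands in for the analytic Karlin–Altschul pairwise
p-value, a documented approximation. Run-length scoring makes outer
fragments weak detectors of highly diverged donors (interruptions break
runs) — consistent with outer fragments rarely reaching significance in
practice — so the constructed-splice test in the suite checks fragment
location rather than significance.

## Population genetics on dominant presence/absence data

* **Binary F~ST~** (`fstBinary`): Weir–Cockerham-style variance components
  on band frequencies, each allele one dominant locus; the multi-locus
  estimate is the ratio of summed components and 95% CIs come from
  bootstrapping loci (20000 by default). No recessive-frequency
  transformation is applied by design — the estimator works on the binary
  encoding directly; a Zhivotovsky-type correction would be a separate
  preprocessing step.
* **Haplotype F~ST~** (`fstHaplotype`): (H~T~ − H~S~)/H~T~ on allele
  frequency vectors built from carrier counts; whether the
  total-population vector averages populations equally or
  carrier-weighted is a flag, since the original software's normalization
  is ambiguous.
* **Codominant F~ST~** (`fstMicrosat`): standard multiallelic
  Weir–Cockerham θ.
* **Admixture** (`admixtureInfer`): a Gibbs sampler for the admixture
  model with independent allele frequencies and fixed Dirichlet α = 1 —
  each allele copy (codominant) or band observation (dominant) carries a
  latent cluster of origin with Dirichlet/Beta conjugate updates. The
  correlated-frequency prior is not implemented (documented limitation);
  the independent-frequency sampler is validated first-class by recovery
  tests. ln P(X|K) is estimated as mean(lnL) − var(lnL)/2 over post-burn-in
  sweeps, and Evanno's ΔK = mean|L(K+1) − 2L(K) + L(K−1)|/SD[L(K)] selects
  K. Replicate runs are aligned by exhaustive label permutation against
  the first run (fine for K ≤ 6) and averaged. Defaults are desk-scale
  (2000 sweeps); the study-scale setting (4×10⁶ replications, burn-in
  4×10⁵, K 1–10, several runs) is reachable through the same arguments.
* **Mantel test**: Spearman correlation of off-diagonal distances with
  row/column permutation, delegated to `vegan::mantel`.
* **Diversity**: per-population allele counts, private alleles, mean
  alleles per specimen; microsatellite allelic richness by hypergeometric
  rarefaction to the smallest population at or above the floor (default
  N > 8; smaller populations are "not evaluated"), and the Spearman
  correlation between marker systems.

## Pipeline

`runPipeline()` chains simulate → genotype → phylo → selection/geneconv →
popgen under a single config (all thresholds above, all seeds derived from
one master seed with fixed offsets per stage, so stages are independently
reproducible), writes per-stage TSV/FASTA/Newick outputs and a JSON
manifest with seeds, thresholds and MD5 digests. `generateReport()`
renders the TSVs — never recomputing — into a plain-text report with
population-summary, dN/dS and model-fit sections, and is idempotent.
Site-model fitting is off by default in the pipeline (it is the one
stage whose runtime depends strongly on cohort size) and switched on with
`fit_site_models = TRUE`.

## Validation problem sizes

The acceptance suite fixes these conditions once: M0 ω-recovery at 40
sequences × 92 codons over 10 seeds (mean relative error ≤ 15%); M1a/M2a
LRT null calibration at 6 taxa × 40 codons × 200 replicates (type-I ≤
0.07 at α = 0.05 — the boundary null makes the χ²₂ reference
conservative); BEB recovery at 24 taxa × 60 codons with 10 planted sites
at ω = 8 and total tree length 12 substitutions/codon (≥ 8/10 at
P > 0.95, ≤ 1 false positive); gene-conversion null calibration over 200
recombination-free pools at 200 permutations; genotyping recall on
noiseless reads (exact) and at 1% error + 5% chimeras with coverage
500–800 (≥ 95% for alleles at ≥ 10% within-amplicon frequency); admixture
recovery at 25 loci, 40+40 individuals plus 10 hybrids at F = 0.5
(assignment accuracy ≥ 95%, ΔK peak at K = 2).

## Known limitations

* No homopolymer-indel error model; frameshift exclusion is length-based.
* The artefact check explains chimeras only as single-crossover
  recombinants of co-occurring variants; multi-crossover chimeras would
  need the permutation machinery of the gene-conversion module.
* The admixture sampler's independent-frequency prior will under-share
  information between closely related clusters relative to the correlated
  F-model; for strongly diverged clusters (the regime validated here) the
  difference is immaterial.
* Codon-model branch lengths are a scaled NJ skeleton, not per-branch
  MLEs; log-likelihoods are therefore not directly comparable to fits
  with free branch lengths, though LRTs between models sharing the
  skeleton are.
* BEB for M8 interpolates beta-class likelihoods; posterior probabilities
  very close to the 0.95/0.99 thresholds should be read with that in
  mind.
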