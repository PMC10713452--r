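---
title: "Multi-protease proteogenomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-protease proteogenomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isocover` re-implements the downstream computation of a deep multi-protease
proteome survey: in silico digestion and coverage accounting, SAP detection
from read pileups and peptide evidence, splice-graph detection of
alternative-splicing (AS) events from junction-spanning peptides, de novo
proteome assembly by reverse translation, and a detectability classifier.
This vignette explains the models and assumptions behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Digestion and coverage

A protease is described by a residue set, a cut side (C- or N-terminal to
the residue) and an optional blocking rule. Defaults are the standard
specificities: trypsin C-terminal to K/R, LysC C-terminal to K, LysN
N-terminal to K, AspN N-terminal to D, GluC C-terminal to E, chymotrypsin
C-terminal to F/W/Y/L. Two parameters dominate everything downstream:

* the **missed-cleavage allowance** (2 for all enzymes, 4 for chymotrypsin,
  matching common search settings for these enzymes), and
* the **detectability window** of 7–35 residues, the size range a shotgun
  MS experiment can realistically identify.

Design choices where the convention was open:

* **Proline rule.** Whether a cut is suppressed before proline is applied by
  default to trypsin, LysC, GluC and chymotrypsin and is togglable
  (`protease_rules(proline_rule = FALSE)`). Published theoretical counts for
  human proteomes depend on this setting; the package exposes both so the
  matching setting can be documented when the reference proteome is
  available (see "Limitations").
* **Non-standard residues** (U, X, B, Z) are treated as non-cleavable
  ordinary residues so coverage denominators stay well defined.
* **Initiator methionine** is not specially removed.
* **Coordinates** are 0-based half-open internally (cleavage sites are
  between-residue positions) and 1-based inclusive in all tabular output,
  the convention of the surrounding genomics tooling.

Observed coverage marks **all** occurrences of each evidence peptide in its
designated protein, ignoring enzyme specificity, and divides marked residues
by protein length. Isoleucine and leucine are kept distinct: matching is
against a designated protein, not a database search. The protease-combination
scan scores every subset of 2–5 enzymes by median per-protein coverage
(median with linear interpolation for even counts) and breaks ties
lexicographically so rankings are reproducible.

## SAP calling

Pileup rows pass iff depth ≥ 10, variant reads ≥ 5, variant frequency
≥ 15 %, base quality ≥ 13, mapping quality ≥ 13 and the site is not
multi-mapped — all boundary values inclusive, each threshold independently
relaxable, and the pass set provably monotone in every threshold (tested).
Passing calls are applied to every isoform CDS containing the site; a
nonsynonymous change yields exactly one substituted residue per affected
isoform, emitted as a `>isoform|VAR=E10K` entry. Heterozygous sites are
represented by keeping both the reference and the variant entry: the 15 %
frequency floor deliberately admits heterozygotes, so dropping the reference
would misclassify reference-allele peptides. No combinatorial haplotypes are
built — one variant per entry avoids exponential blow-up and matches how
variation-aware search engines consume these files.

Peptide classes follow the variation-aware search convention: `Yes` if the
peptide covers a substituted residue with the variant amino acid and does not
occur in the reference proteome, `Mixed` if it covers a substituted residue
but also occurs somewhere in the reference, `No` otherwise. A SAP counts as
proteomics-detected iff at least one `Yes` peptide covers its residue.

The deleteriousness shift between detected and undetected SAPs uses a
two-sided Wilcoxon rank-sum test (normal approximation, midranks, tie-
corrected variance; a fully tied input returns p = 1). Score category bins
are configurable; defaults are the conventional SIFT cut-points
(0.05/0.1/0.2) and the published PolyPhen bins (0.446/0.908). The scores
themselves are consumed from input — computing them is out of scope.

## Splice graphs, projection and PSI

Gene graphs have one node per exon start/end and two edge types: intra-exon
and junction. Each isoform is a path; an AS event is a local subgraph where
two or more isoform sub-paths leave a shared anchor node and reconverge only
at a shared downstream anchor. Events are keyed by their anchor pair so the
same bubble reached through several isoform pairs is counted once; the
enumeration is verified against a brute-force anchor search on random
graphs. Types are assigned from path topology, and frame status from the
exonic-length difference between paths (frame-preserving iff divisible by
3). Junction classes are total: constitutive iff present in every isoform;
otherwise exclusion if the junction is itself the skip path of an event,
inclusion otherwise.

Peptides are projected to the genome through their isoform's CDS blocks:
residues *s..e* occupy CDS nucleotides `[3(s-1), 3e)`, split across exon
blocks; minus-strand blocks are reported with ascending coordinates inside
each block, in transcript order, and the projection is required to
re-translate to the source peptide (a property held by 100 % of synthetic
peptides in the tests). Numerical choices:

* **Junction flank**: a peptide supports a junction iff its projection
  crosses it with ≥ 3 nt (one codon) on each side, configurable. One codon
  guarantees at least one amino acid of junction-specific context; support
  is monotone non-increasing in the flank.
* **Codons split across junctions** still count as spanning — crossing is
  defined at the nucleotide level.
* **PSI** is the inclusion fraction with the two inclusion junctions
  averaged: `PSI = mean(i1, i2) / (mean(i1, i2) + excl)`; zero total reads
  give `NA`, never 0.
* **Expression bins** for detection-rate tables are integer log2 bins;
  log2 RPKM ≥ 7 is the "relatively abundant" threshold.

The detectability argument for PSI: at equal per-junction efficiency the
inclusion isoform contributes two detectable junctions (signal ∝ 2·PSI) and
the exclusion isoform one (∝ 1−PSI). The balance point solves
2·PSI = 1−PSI, i.e. PSI = 1/3 (33 %). `psi_detection_optimum()` solves this
with a root finder and confirms it by simulating Bernoulli detection on a
PSI grid; because both expected rates are linear in PSI, the crossing is
estimated from a linear fit of the rate difference rather than the argmax of
the noisy pointwise minimum, which is sensitive to grid resolution.

## De novo assembly

Peptides are reverse-translated with a nondegenerate codon map (default: the
most frequent human codon per residue). Because the map is an injective,
stop-free bijection, assembly operates on an alphabet-inflated copy of
peptide space, and any fixed map yields isomorphic graphs — asserted in the
tests by checking that two different maps give identical matched contig
translations. The assembler is a minimal deterministic de Bruijn unitig
assembler (k = 23 nt, spanning ≥ 8 residues; minimum contig 100 nt,
spanning ≥ 34 residues; reads capped at 150 nt): contigs are maximal
non-branching paths of the k-mer graph, no tip or bubble removal, output a
pure function of the k-mer set (read-order invariant; cycles broken at the
lexicographically smallest k-mer). Determinism and testability were chosen
over contiguity. Two consequences worth knowing:

* a unitig may start at any phase within a codon, so scaffold matching
  translates in all three frames and accepts a scaffold when some frame is
  an exact substring of a proteome entry (the spanned-residue count
  `ceiling(nt/3)` is reported);
* splice bubbles and coverage gaps break unitigs, and pieces below the
  100 nt floor are discarded, so recovered CDS fraction is measured against
  each gene's coding sequence counted once (its all-exon isoform) — the
  skip-isoform entries repeat the same genomic CDS minus one exon and would
  double-count it.

## Detectability classifier

Features per cassette event: log2 transcript abundance, PSI, cassette exon
length, CDS length, frame flag, and one junction-coverage feature per
protease — the minimum over the two isoforms of the fraction of residues
within 35 aa of the isoform's event junction(s) that are coverable by fully
specific, in-window digestion peptides. The 35 aa half-width (the maximum
detectable peptide length) is a package choice; the feature is configurable
because no canonical definition exists.

The learner is a self-contained second-order gradient-boosted tree
implementation honouring the tuned hyperparameters (learning rate 0.05,
L1 1.15, L2 4.0, min child weight 2.0, depth 3, gamma 2.0, colsample 0.3,
subsample 0.65, positive-class weight 4.44): logistic loss,
gradient/hessian split gains with L1 soft-thresholding and L2 shrinkage,
gamma pruning, per-tree row/column subsampling. No gradient-boosting
package is available in the supported environment, and the finding this
module reproduces is a feature ranking, not a weights artifact, so the
backend is specified by contract and kept pluggable. Evaluation is
stratified sevenfold cross-validation with per-fold ROC/AUC and pooled
out-of-fold AUC; permutation importance is the mean AUC drop over 100
shuffles per feature.

## The synthetic world

`synth_config()` states the world once; its defaults are not tuned to tests:

* 50 genes, 3–8 exons of 30–150 nt (codon-aligned by default), introns
  40–200 nt, both strands, one chromosome. Codons are sampled uniformly from
  the 61 non-stop codons, avoiding composition bias in digestion tests.
* Each internal exon is a cassette exon with probability 0.35; cassette
  lengths are multiples of 3 with probability 0.5 (the frame-preserving
  fraction). A frame-breaking skip isoform is translated until its first
  premature stop and truncated there — emulating the fate of a
  frameshifted message — with the truncation recorded in the model, so
  every emitted protein is stop-free. Frame-preserving skip isoforms are
  guaranteed stop-free by resampling the CDS until junction codons are
  clean.
* PSI per cassette exon is uniform on [0.05, 0.95]; isoform weights within
  a gene follow from the PSI values.
* Nonsynonymous SNPs are planted at 2 per kb of CDS with negative-binomial
  depth (mean 30), a heterozygote-centred allele-fraction mixture with a
  20 % low-frequency component, and Gaussian base/mapping qualities.
  The drawn allele fraction is realised exactly
  (`alt = round(depth * freq)`), so constant-frequency configurations give
  deterministic filter outcomes.
* Gene abundance is log-normal (log2 mean 3, sd 2), an RPKM-like spread.
  Peptide detection is logistic in log2 isoform abundance with per-protease
  efficiency offsets. The intercept/slope (−5.5, 0.8) were calibrated once
  so that roughly a fifth of cassette events gain junction-peptide support
  on both paths — the magnitude deep proteomics actually observes — and
  then left alone; the functional form is a stand-in, not an inference of
  any published model.
* Junction reads: each gene's budget is proportional to abundance;
  inclusion support is drawn as Binomial(2N, PSI) and split evenly across
  the two inclusion junctions, exclusion as Binomial(N, 1−PSI), which makes
  the averaged-inclusion PSI estimator unbiased and encodes the
  two-junction opportunity of the inclusion isoform.

What the generator does **not** emulate: spectra and search-engine errors
(evidence is planted truth, never false); sequencing error profiles;
modifications; multi-gene families and shared peptides across genes;
overlapping genes; indels or splice-site variants. A green test therefore
establishes algorithmic correctness on data with the assumed statistical
structure, not robustness to real-data artifacts.

## Degenerate inputs and tie-breaks

Empty proteins digest to empty sets; zero-read events have undefined (`NA`)
PSI; evidence peptides absent from their designated protein are skipped with
a warning and counted; a fully tied rank-sum input returns p = 1; subset
rankings, assembly output and fold assignments are deterministic under a
fixed seed; all generator outputs are byte-identical for a fixed seed.

## Limitations

* The UniProt-scale theoretical digestion numbers (≈ 2.3 M tryptic
  peptides, 86 % → 99 % residue coverage) require the pinned UniProt
  2017_02 canonical human proteome. Offline runs cannot fetch it; the
  acceptance test for that criterion fails with an explanatory message
  rather than skipping, and the proline-rule setting that reproduces the
  printed values therefore remains undetermined here. When the file is
  placed at `scratch/UP000005640_2017_02_canonical.fasta` the test computes
  all four numbers under the default (proline rule on) and the toggle is one
  argument away.
* The headline dataset results (17,717 proteins, 79.2 % median coverage,
  1,119,510 unique peptides, 73 % SAP confirmation at the protein level,
  classifier AUC 0.83) depend on the deposited raw data and are
  non-reproduced context, not targets, for this package.
* Event enumeration assumes isoforms share exon boundaries where they share
  sequence; fuzzy boundaries from imperfect annotation are not modelled.
* The assembler's pure-unitig policy fragments contigs at every bubble; a
  scaffolding stage could recover contiguity but would trade away the
  determinism the tests rely on.
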