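Package: isocover
Title: Multi-Protease Proteome Coverage, Variant Peptides and Splice-Isoform Detection
Version: 0.1.0
Authors@R:
    person("Ivan", "Kovar", email = "ivan.kovar@example.org", role = c("aut", "cre"))
Description: Downstream proteogenomics toolkit for deep multi-protease
    shotgun proteomics. Performs in silico digestion with six proteases
    (trypsin, LysC, LysN, AspN, GluC, chymotrypsin) with missed cleavages
    and a mass-spectrometry length window; computes theoretical and
    observed protein sequence coverage, protease-combination scans and
    transmembrane-segment coverage profiles; calls single amino acid
    polymorphisms (SAPs) from read pileups with a depth/frequency/quality
    filter cascade, builds variant proteomes and classifies variant
    peptides; constructs exon-boundary splice graphs, enumerates
    alternative-splicing events, projects peptides to genomic coordinates
    and quantifies junction-level detection against expression and
    percent-spliced-in (PSI); assembles proteomes de novo by
    reverse-translating peptides through a nondegenerate codon table into
    a de Bruijn unitig assembler; and trains a gradient-boosted classifier
    of event detectability with cross-validation and permutation
    importance. A synthetic-data module generates genomes, gene models,
    variants, junction reads and peptide evidence with the statistical
    structure the analysis assumes, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
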