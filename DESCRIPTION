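Package: gvmag
Title: Recovery, Refinement and Population Ecology of Giant Virus Genomes
    from Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for genome-resolved metagenomics of giant viruses
    (Nucleocytoviricota). Screens metagenomic bins with a weighted
    core-gene density index, refines candidate bins through a multi-rule
    quality-control cascade (characteristic scoring, bin removal,
    two-stage contig decontamination, chimera detection and splitting),
    dereplicates genomes at the 95% average nucleotide identity species
    boundary, scores genome quality against phylogenetically defined
    clades (consistency and redundancy relative to clade core genes), and
    quantifies population ecology and microdiversity: RPKM abundance,
    presence and abundance calling, Shannon/Simpson diversity,
    Sorensen-Dice community recurrence, niche-breadth classification with
    Levins' index, per-site nucleotide diversity, SNV density, and the
    fixation index between samples. Seeded synthetic-data generators with
    planted ground truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
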