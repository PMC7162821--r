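Package: hugephage
Title: Discovery and Characterization of Huge Phage Genomes from
    Metagenomic Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and characterizes very large (>=200 kb) phage and
    plasmid-like genomes among long metagenomic contigs. Implements assembly
    quality control (end-overlap circularization, tandem-concatemer artifact
    detection, exact repeat tabulation, GC-skew replication-mode profiling and
    origin-based reorientation), minimal ORF calling with inference of
    alternative genetic codes (stop-codon reassignment), element-type
    classification by taxonomy voting and marker genes, de novo CRISPR array
    detection with spacer-protospacer matching and interaction networks,
    host-phylum prediction, and two-step protein-family clustering (greedy set
    cover followed by Markov clustering). A synthetic-community generator
    plants every one of these genomic features with a machine-readable ground
    truth so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    IRanges,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metagenomics, Annotation, Classification, QualityControl
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'crispr.R'
    'families.R'
    'genes.R'
    'hosts.R'
    'io.R'
    'pipeline.R'
    'qc.R'
    'simulate.R'
    'utils.R'
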