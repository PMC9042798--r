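Package: CircleSeqTools
Title: Circle-Seq eccDNA Detection, Characterization and Cohort Comparison
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Detection and characterization of extrachromosomal circular DNA
    (eccDNA) from Circle-Seq sequencing data. Implements junction-evidence
    circle calling from split reads and discordant read pairs with a
    six-criterion confidence filter, per-million-mapped-reads (EPM)
    normalization, genomic and sequence characterization (GC content versus
    flanking regions, fragment-size periodicity, genomic-element and repeat
    enrichment against a chromosome-length-weighted random null,
    per-chromosome density correlations), junction microhomology analysis
    (direct repeats and trinucleotide palindromic units), miRNA-gene circle
    recurrence, and two-group cohort comparison. A seed-reproducible
    Circle-Seq read simulator (circular templates, junction-spanning split
    alignments, discordant pairs, linear background) supports validation of
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
biocViews: Sequencing, Coverage, StructuralVariation, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
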