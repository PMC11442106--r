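Package: polyBSA
Title: Polyploid QTL-seq Bulked Segregant Analysis for Autopolyploid F1 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical core of polyploid QTL-seq for bulked segregant analysis
    in autopolyploid (e.g. autohexaploid) F1 populations. Classifies parental
    variants by allele dosage (simplex, duplex, triplex) from allele-read
    fractions, computes per-bulk SNP-index and delta SNP-index statistics,
    derives confidence thresholds and P values from a plexity-adapted
    polysomic-segregation null simulation, scans the genome in sliding windows
    with directional QTL-variant counts, calls candidate QTL regions by a
    two-criterion rule, and nominates allele-specific marker SNPs. Includes a
    synthetic hexaploid-cross simulator (polysomic inheritance via random
    bivalent pairing, optional crossovers, additive QTL phenotypes,
    extreme-phenotype bulking, binomial read sampling) so the whole pipeline is
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
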