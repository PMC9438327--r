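Package: picnc
Title: Prediction of Mutation Impact by Calibrated Nucleotide Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates nonsynonymous point mutations in protein-coding genes
    from sequence alone, predicts phylogenetic nucleotide conservation (PNC)
    with weighted probability random forests under leave-one-chromosome-out
    validation, and uses predicted conservation as truncated SNP weights in
    two-kernel GBLUP genomic prediction with a permutation significance test.
    Includes a synthetic-data generator (genome, gene models, conservation
    scores, SNP panels, phenotypes) with planted statistical structure so the
    whole pipeline can be exercised and validated without external downloads,
    plus gene-level functional enrichment statistics (expression contrasts,
    Fisher term enrichment, Pn/Ps).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
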