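Package: nucredit
Title: Nuclear RNA-Editing Site Calling, Characterization and
    PPR Coexpression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies RNA-editing sites from transcript-space base-count
    pileups using a coverage filter, a Fisher's exact test against the
    sequencing-error expectation and Benjamini-Hochberg FDR control;
    characterizes called sites by substitution type, transcript region,
    codon position, synonymy, editing degree and editing density; tests
    GO-term and endosymbiont-derived-gene enrichment of edited genes;
    clusters pentatricopeptide-repeat (PPR) genes with C-to-U edited
    target genes through a Shared Coexpression Matrix decomposition; and
    scans the +/-5 flanks of edited C residues for a conserved core motif
    by positional chi-square tests against a transcriptome background.
    A synthetic-data generator produces every input the pipeline consumes
    with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
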