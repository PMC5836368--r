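Package: juncpep
Title: Protease Cleavage Specificity and Splice-Junction Peptide Detectability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how protease cleavage specificity limits the
    detection of exon-exon junction-spanning peptides in shotgun proteomics.
    Parses coding gene models (genePred or GTF) against a genome FASTA into
    codon-resolved transcript-to-genome maps, enumerates unique coding splice
    junctions with reading-frame phase and boundary residue, computes amino-acid
    composition and enrichment at exon boundaries, lysine/arginine junction
    statistics, splice-site nucleotide frequency matrices, and frame-adjusted
    cleavage-scenario probabilities. Performs in-silico digestion with
    configurable protease rules (trypsin, chymotrypsin, Glu-C, Lys-C, Asp-N,
    Arg-C presets), projects peptides to genomic block coordinates, and
    summarises per-enzyme CDS, junction, and K/R-junction detectability,
    multi-enzyme overlap, observed-peptide type classification, and
    boundary-distance enrichment. Includes a synthetic genome and annotation
    generator with controllable splice-boundary biases so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
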