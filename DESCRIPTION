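Package: tgintegrity
Title: Transgene Integration Sites and Genome-Wide Small-Variant Analysis
    for Resequenced Transgenic Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess transgene integration and genome-wide small
    variation in resequenced transgenic plant lines. Detects T-DNA
    insertion sites, junction-deletion lengths, copy number and insert
    structure from paired-end alignments against a combined genome+vector
    reference; builds a dual-caller variant consensus with an explicit
    filter cascade (low-complexity DUST masking, quality, depth and
    strand-balance filters, normalization to primitive alleles and
    callset intersection); annotates variants with genomic region,
    coding effect and impact tier on canonical transcripts; and computes
    the standard summary statistics (variation rate, type spectrum,
    Ts/Tv, indel spectra, region densities, 10-kb binned distributions,
    hotspot contigs, three-line comparisons and verification precision).
    Includes a seeded synthetic-data generator (annotated toy genomes,
    transgenic derivatives, planted variant spectra, paired-end reads
    with truth alignments, and emulated caller outputs) so the whole
    pipeline is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
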