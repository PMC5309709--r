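Package: strseq
Title: Probe-Indexed Targeted Sequencing Analysis of Short Tandem Repeats
Version: 1.0.0
Authors@R:
    person("STRseq", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for probe-indexed targeted sequencing of
    microsatellites (short tandem repeats). Read pairs are assigned to
    their target STR through the alignment position of the primer-probe
    read (Read 2), repeat counts are measured on Read 1 between exact
    15-base flanking sequences, and diploid genotypes are called with
    stutter-aware read-count thresholds keyed by allelic distance.
    Proximal SNPs called from probe-masked Read 2 pileups are phased
    with repeat alleles into read-backed STR-SNP haplotypes, supporting
    mixture deconvolution, trio concordance, and capillary
    electrophoresis comparison. Includes a paired-end read simulator
    with configurable stutter and CRISPR-targeted versus random
    fragmentation models, and panel design filters for probes and
    guide RNAs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
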