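Package: ampliphase
Title: Read-Backed Phasing and Allelic Expression from Targeted cDNA
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Ampliphase", "Developers", email = "ampliphase@example.org",
           role = c("aut", "cre"))
Description: Determines whether two heterozygous variants on a targeted
    cDNA amplicon lie on the same allele (in cis) or on opposite alleles
    (in trans) from paired-end sequencing reads, and quantifies
    differential allelic expression at each site.  Reads are assigned to
    alleles by exact matching of short distinguishing sequence contexts
    around each variant, PCR duplicates are collapsed with unique
    molecular identifiers (UMIs) before any counting, and phase is called
    from the two-site haplotype configuration table.  A paired-end
    amplicon read simulator with per-read ground truth provides all test
    inputs, including the contrast between direct adapter ligation and
    tagmentation-style library preparation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
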