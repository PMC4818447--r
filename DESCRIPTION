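Package: recessmap
Title: Mapping Recessive Defects from Array Haplotypes and Sequence Variants
Version: 1.0.0
Authors@R: person("recessmap", "maintainers", email = "recessmap@example.org",
    role = c("aut", "cre"))
Description: A pipeline for mapping recessive monogenic defects in livestock
    populations: SNP-array quality control, sliding-window haplotype
    association with Fisher exact allelic tests and Bonferroni control,
    autozygosity (runs-of-homozygosity) mapping, recessive-compatibility
    filtering of sequence variants with cross-population exclusion,
    coding-consequence prediction (frameshift translation, HGVS naming,
    intron-retention transcripts, in-silico RT-PCR) and supporting
    population statistics.  Includes a gene-dropping cohort simulator and
    an engineered disease-gene fixture so the whole chain is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb
Config/testthat/edition: 3
RoxygenNote: 7.3.3
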