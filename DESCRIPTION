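Package: metagsim
Title: Metagenomic Read Simulation and Assembly Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates shotgun metagenomic sequencing reads for Sanger,
    pyrosequencing and Illumina platforms with platform-specific quality
    and base-error models, recording full ground-truth provenance for
    every read. Communities are built from rank-abundance models and
    sequencing effort is allocated per genome by abundance times genome
    length. Companion assessment tools score assemblies of the simulated
    data against the truth: Illumina-style quality trimming and
    filtering, k-mismatch read-back mapping and genome coverage,
    chimericity measures, Contig Score, N50 and contig-length summaries,
    scaftig extraction, and comparison of functional-category abundance
    profiles via Jensen-Shannon divergence, principal coordinate
    analysis, principal component analysis and Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
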