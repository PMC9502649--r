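Package: sdrscan
Title: Sex-Determination Region Mapping and Sex-Chromosome Divergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of sex-determination regions (SDRs) from sexed
    population genotype and depth data, identification of Y-specific
    sequence via sex-specific k-mers and read-backed phasing, X-Y
    gametolog divergence (Nei-Gojobori Ka/Ks) and strata assessment,
    Kimura two-parameter dating of LTR retrotransposon insertions, SDR
    gene classification, and deleterious-mutation-load comparison.
    Ships a synthetic-cohort generator with planted ground truth so the
    whole pipeline is testable end to end without external sequencing
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
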