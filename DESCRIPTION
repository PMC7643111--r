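Package: picspec
Title: Protease Cleavage-Site Specificity Profiling from Peptide Libraries
    and Protein Substrate Digests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs complete P6-P6' protease cleavage sites from
    proteome-derived peptide-library degradomics experiments (PICS) and from
    digests of defined protein substrates, including the sequential
    trypsin-assisted protocol, and summarises subsite specificity as
    relative-occurrence and fold-enrichment heat-map matrices and
    percent-difference (iceLogo-style) profiles with per-cell significance.
    Includes an in-silico digestion engine (trypsin, GluC, user-defined
    enzymes), stable-isotope dimethyl channel bookkeeping, peptide-to-protein
    mapping with sequence-coverage maps, unique-site set algebra across
    experiments, and a ground-truthed simulator of the full experimental
    design so every stage of the pipeline can be verified by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
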