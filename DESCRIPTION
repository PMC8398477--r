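Package: nppipe
Title: Neuropeptide Precursor Discovery, Prohormone Processing and
    Stage-Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for mining neuropeptide precursor proteins (NPPs) from
    transcriptome assemblies of invertebrate neural tissue. Provides
    six-frame ORF extraction, a transparent signal-peptide heuristic,
    local-alignment homology screening with E-value and NPP feature filters,
    prohormone convertase cleavage prediction with C-terminal amidation and
    N-terminal pyroglutamate annotation, monoisotopic peptide mass matching
    against mass-spectrometry observations with target-decoy FDR control,
    TPM normalization with stage-wise ANOVA/Tukey testing and
    expression-profile classification, and fully seeded synthetic-data
    generators with known ground truth for every stage of the pipeline.
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
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
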