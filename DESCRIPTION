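Package: protoquant
Title: Quantification of Base-Editing Outcomes in Arrayed Protoplast Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-content quantification of CRISPR base-editing
    experiments in plant protoplasts. Simulates arrayed 96-well plate
    acquisitions (multi-channel, multi-Z fluorescence fields with known
    ground truth) and amplicon read sets with specified allele mixtures;
    segments protoplasts from the chlorophyll channel with a roundness
    filter, detects nuclei from the mCherry/GFP reporter channels, and
    gates transfected and edited cells; computes per-well and per-condition
    editing efficiencies with the comparison tests used in reporter-based
    screens; and quantifies substitutions, indels, alleles, and zygosity
    from amplicon sequencing with an explicit quantification-window
    parameterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
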