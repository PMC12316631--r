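Package: peptaibr
Title: Peptaibiomics: Mass Calculus, Fragment Ladders and De Novo
    Assembly for Peptaibol LC-MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the mass-spectrometric characterisation of
    peptaibols and lipopeptaibols, the Aib-rich nonribosomal peptides of
    Trichoderma and related fungi. Provides a monoisotopic mass calculus
    for sequences built from nonproteinogenic residues (Aib, Iva, C-terminal
    amino alcohols, N-terminal acetyl or octanoyl caps), theoretical b/y
    fragment-ion ladders including the diagnostic in-source Aib-Pro
    cleavage pair, de novo sequence assembly from observed MS2 fragment
    ladders with residual-mass reporting, novelty annotation against a
    reference sequence database with substitution notation and
    module-skip gap alignment, relative quantification of a strain's
    peptaibiome from extracted-ion-chromatogram peak areas, consensus and
    microheterogeneity analytics, and a seeded synthetic-spectrum
    generator so every pipeline stage can be tested without instrument
    data. Reads and writes MGF peak lists and TSV compound tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
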