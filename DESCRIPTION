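Package: mrmiso
Title: Positional Isotopomer Analysis of Glutamate and Aspartate from MRM Tandem Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs the complete positional carbon-13 isotopomer
    distributions of glutamate (32 isotopomers) and aspartate (16 isotopomers)
    from LC-MS/MS multiple-reaction-monitoring (MRM) peak areas. Fragment-ion
    combinatorics over declared precursor/product transition families define a
    linear map from isotopomer fractions to ion-pair intensity fractions;
    naturally occurring heavy isotopes (2H, 13C, 15N, 17O, 18O) are modelled by
    convolving per-element isotope distributions into an augmented mapping
    matrix; the rank-deficient inverse problem is solved by bounded nonnegative
    least squares. Includes a simulation survey that quantifies per-isotopomer
    identifiability, a minimal TCA-cycle labeling simulator for generating
    ground-truth test data, and closed-form TCA readouts (F_C3, anaplerosis,
    NMR multiplet aggregation, pyruvate-carboxylase and fumarate-hydratase
    diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    pracma,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
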