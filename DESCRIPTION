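Package: ippdyn
Title: Absolute Inositol Pyrophosphate Quantification and PHO Pathway
    Activation Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring absolute cytosolic inositol pyrophosphate
    (1-IP7, 5-IP7, 1,5-IP8) concentrations from capillary-electrophoresis
    MRM peak tables by isotope dilution against co-injected 13C-labelled
    standards, with spike-in recovery correction and cell-volume
    normalisation; for segmenting yeast cells and nuclei in multi-channel
    fluorescence fields and quantifying per-cell nuclear/cytosolic reporter
    ratios; for fitting exponential-decay and logistic-relocation kinetics
    and inferring the repressive concentration threshold; and for
    normalising plate-reader reporter fluorescence with the group
    comparisons used alongside. A synthetic-data module generates all
    fixture inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
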