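Package: swathdia
Title: SWATH-MS Label-Free Quantification, Cohort Stratification and
    Diagnostic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for SWATH/DIA label-free
    proteomics case-control studies: fragment-ion to protein rollup (top
    fragments of top peptides), total-sum normalization, technical-replicate
    averaging, two-group differential abundance with p-value and log10
    fold-change threshold filters, square-root/Pareto-scaled principal
    component analysis for cohort stratification, principal-component
    logistic-regression classification validated by leave-one-out
    cross-validation with a label-permutation significance test, and a
    size-matched random-panel specificity test for annotated protein sets.
    Includes a fragment-level synthetic cohort generator with planted
    effects and a planted case subgroup so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
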