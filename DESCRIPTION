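Package: deathconcord
Title: Multi-Source Mortality Record Linkage and Death Concordance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing how consistently patient deaths are captured
    across two health systems and a Social Security Administration Death
    Master File (SSADMF) style extract. Provides privacy-preserving record
    linkage with keyed hash tokens (including American Soundex phonetic
    encoding), cross-system deterministic matching, eight-category death
    concordance classification with Venn-region export, Fleiss kappa
    multi-rater agreement with asymptotic and bootstrap confidence intervals,
    three exploratory data-quality detectors (lost-contact patients,
    cross-source death-date discrepancies, post-death encounters), and a
    seed-reproducible synthetic cohort generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    openssl,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
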