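Package: myoconcord
Title: Two-Sex Muscle-Aging Transcriptome Concordance and Fiber Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sex differences in skeletal-muscle aging
    from bulk transcriptome data: median-of-ratios normalization, per-sex
    old-versus-young negative-binomial differential expression, partitioning
    of differentially expressed genes into shared and sex-specific sets,
    cross-sex direction-of-regulation concordance statistics (sign
    agreement, correlation, regression slope), gene-set-restricted
    concordance, and probe-to-gene collapse for harmonizing external
    microarray cohorts. Includes a negative-binomial count simulator with
    known two-sex effect structure, a synthetic immunofluorescence section
    renderer, and fiber-typing morphometry based on the minimal Feret
    diameter.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
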