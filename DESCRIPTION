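Package: somex
Title: Quantification of Age-Dependent Somatic CAG Repeat Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying somatic expansion of CAG trinucleotide
    repeats from capillary-electrophoresis fragment peak tables. Provides
    Gaussian allele-peak deconvolution by separable (variable projection)
    least squares, inherited-allele normalization into somatic repeat-change
    distributions, pooled quantile-cell genotype comparisons with
    animal-level bootstrap errors, age-window expansion summaries, and
    rotarod/grip phenotype analyses including covariate regression,
    percentile-performance association and onset-delay detection. A
    synthetic cohort generator emulates inherited-allele variation,
    tissue- and age-dependent expansion, PCR stutter ladders and the
    motor-testing protocol, so the full pipeline is testable end to end.
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
    withr
Config/testthat/edition: 3
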