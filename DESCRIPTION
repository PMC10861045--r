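Package: triomu
Title: Trio-Based Germline Mutation Rate Estimation and Population-Size Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of de novo mutations (DNMs) from parent-offspring trio
    genotype data with a configurable filter cascade (site-quality filters,
    Mendelian-violation selection, trio-level allelic-depth/genotype-quality/
    depth/allelic-balance filters, an independent genotype-likelihood recall,
    a population polymorphism screen and automated curation heuristics),
    callable-site counting and false-negative-rate correction for the
    per-generation germline mutation rate estimator
    mu = (nb_DNM - nb_FP) / (2 * C * (1 - FNR)), mutation-spectrum and
    read-back parent-of-origin phasing summaries, and population-size
    analysis: equilibrium effective size Ne = pi / (4 * mu), harmonic and
    arithmetic trajectory means, bootstrap census-size estimation from reef
    survey tables, and Ne/Nc ratios. A synthetic-data module simulates trio
    sequencing cohorts with planted ground-truth mutations and boom-bust
    reef-survey tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    Biostrings
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
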