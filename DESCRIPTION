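Package: pedscreen
Title: Family-Based Rare-Variant Prioritization for Dominant Disorders
    with Incomplete Penetrance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rare candidate variants in disease
    pedigrees sequenced by whole-exome sequencing. Implements pedigree role
    classification (blood members, marry-ins, obligate carriers under a
    dominant model with incomplete penetrance), a three-stage variant filter
    cascade (site quality control, functional/prevalence filtering, and
    segregation filtering), multiplicative MendelScan-style prioritization
    scores (segregation, population, annotation), and ranking of surviving
    candidates. Also provides the companion expression-validation statistics
    (pooled two-sample t-tests from raw values or published summary
    statistics, Kolmogorov-Smirnov normality checks, and comparative-Ct
    qPCR fold changes) and a gene-dropping simulator that generates
    pedigree genotype data with a planted causal variant so that every
    pipeline stage can be exercised without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
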