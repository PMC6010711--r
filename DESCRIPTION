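Package: popcompare
Title: Randomization Tests and Bootstrap Inference for Stage-Structured
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical comparison of demographic parameters among
    stage-structured populations described by projection matrices or raw
    individual demographic data. Computes the asymptotic growth rate, net
    reproductive rate, generation time, stable stage structure,
    reproductive value, sensitivity and elasticity matrices, and the
    composition of individual life histories. Populations are compared
    with randomization (permutation) tests, global or pairwise, including
    planned comparisons among pooled groups; confidence intervals are
    obtained by bootstrap resampling of individual histories; one-way life
    table response experiments (fixed and random designs) decompose
    variation in the growth rate into vital-rate contributions; power of
    the comparison tests is estimated by resampling, and power, p-values
    and confidence-interval width can be explored across increasing sample
    sizes at constant vital rates. Includes a synthetic-data generator for
    stage-fate and recruitment data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
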