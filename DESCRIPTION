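Package: osteokin
Title: Multi-Evidence Identity Testing for Ancient Skeletal Remains
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to decide whether separate ancient skeletal elements derive
    from one individual, combining pseudo-haploid genotype relatedness
    (pairwise mismatch rate with a half-baseline identity rule), outgroup-f3
    shared-drift statistics with weighted block-jackknife standard errors,
    coverage-based genetic sex determination, post-mortem deamination
    profiling and damage-based read filtering, radiocarbon calibration with a
    fraction-modern-carbon contamination mixing model and Ward-Wilson date
    combination, and collagen stable-isotope quality control with
    trophic-offset evaluation. A synthetic-data generator with known ground
    truth lets the whole pipeline run and be tested without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
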