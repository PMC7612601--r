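Package: raswcrt
Title: Response-Adaptive Intervention Allocation in Stepped-Wedge Cluster Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of response-adaptive stepped-wedge cluster
    randomized trials (SW-CRTs). Provides allocation-matrix representation and
    enumeration of admissible continuation designs at interim analyses,
    generalized least squares estimation of the intervention effect under a
    linear mixed model with known variance components, Wald statistics and
    information levels, a binomial patient-benefit score and a weighted
    information/benefit criterion for interim selection of the roll-out,
    Hussey-Hughes power and sample-size determination, and Monte-Carlo
    machinery to estimate operating characteristics (type-I error, power,
    allocation proportions, bias, root-mean-square error) of adaptive and
    fixed designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
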