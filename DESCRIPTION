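Package: decluster
Title: Differential Evolution Clustering with a Diversity-Adaptive Double Mutation
Version: 1.0.0
Authors@R: person("M.", "Laurent", email = "mlaurent@example.org",
    role = c("aut", "cre"))
Description: Partitional clustering by differential evolution over
    center-encoded individuals, minimizing the sum of unsquared
    within-cluster Euclidean distances (WCD). Implements a double-mutation
    scheme that switches between DE/best/1 and DE/rand/1 according to a
    scale-free population-diversity indicator, alongside classical K-Means,
    K-Means++ seeding and a fixed-strategy DE baseline, plus a benchmark
    harness for repeated independent runs on UCI-style tabular data and
    binary drug-prescription co-occurrence matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
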