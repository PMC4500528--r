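Package: gxemis
Title: Gene-Environment Interaction Analysis with a Misclassified Binary
    Exposure and Multiple Markers in Linkage Disequilibrium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genotype-based pseudolikelihood analysis of case-control
    studies of gene-environment interaction when the binary environmental
    exposure is measured with misclassification and several genetic markers
    in pairwise linkage disequilibrium enter the risk model directly
    through additive and dominance codes.  Provides the retrospective
    pseudo-maximum-likelihood estimator with sandwich standard errors, a
    Metropolis-Hastings sampler for the pseudolikelihood-based posterior,
    a large-sample Gaussian approximation of that posterior, a
    posterior-coverage validity check of the pseudolikelihood, a naive
    logistic-regression comparator that ignores misclassification, and a
    simulator for case-control data under Hardy-Weinberg equilibrium with
    pairwise linkage disequilibrium.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
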