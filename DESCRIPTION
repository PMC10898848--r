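Package: kcdtree
Title: Decision-Tree Consensus Analysis for Interlaboratory Key Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Routes the measurement results of an interlaboratory key
    comparison through a decision tree of three gating statistical tests
    (Cochran's Q test of mutual consistency, a bootstrap test of symmetry
    about an unknown median, and Shapiro-Wilk / Anderson-Darling tests of
    Gaussian shape) to one of five consensus estimators: the adaptive
    (DerSimonian-Laird) weighted average, the weighted median, and three
    Bayesian hierarchical random-effects models with Gaussian, Laplace, or
    skew-Student lab effects fitted by Markov chain Monte Carlo. Produces a
    key comparison reference value (KCRV) with its standard uncertainty, a
    Q-profile confidence interval for the dark-uncertainty (between-lab)
    standard deviation, and unilateral degrees of equivalence whose expanded
    uncertainties propagate dark uncertainty and the correlation between
    each laboratory's result and the consensus value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    readr,
    rjags,
    rlang,
    stats,
    tibble
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
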