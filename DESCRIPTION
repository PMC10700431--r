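Package: ordbf
Title: Order-Constrained Bayes Factors for Binomial and Multinomial Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bayesian evaluation of informed hypotheses on category
    proportions from multinomial or independent-binomial count data.
    Hypotheses may combine equality constraints, inequality (order)
    constraints, and free parameters, as long as the constrained elements
    form a linear chain ("stick" hypotheses). Equality constraints are
    handled analytically through conjugate Dirichlet/beta marginal
    likelihoods; inequality constraints are handled by estimating the
    normalizing constants of the order-constrained prior and posterior
    densities with Meng-Wong optimal bridge sampling, using a
    stick-breaking probit transform and a moment-matched multivariate
    normal proposal. Results combine into Bayes factors against the
    encompassing or null hypothesis, posterior model probabilities, and
    prior sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
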