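Package: gravroute
Title: Hybrid Gravity and Route-Choice Modelling of Vector Traffic in Road
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates long-distance vector (agent) traffic in large road
    networks from roadside survey counts by combining a stochastic gravity
    model for origin-destination trip generation with a route-choice model
    over locally optimal paths, a cyclic (von Mises) daily traffic pattern,
    and a survey-compliance model.  Counts follow a negative binomial law
    with a constant mean-to-variance ratio, so that the family is closed
    under pooling of origins or destinations and under the successive
    thinnings of the hierarchical observation process.  The submodels are
    fitted in stages (compliance, temporal pattern, route choice, gravity)
    by conditional and composite likelihood, with profile-likelihood
    confidence intervals and AIC-based covariate selection.  Fitted models
    predict origin outflows, destination inflows with uncertainty
    percentiles, and directed road-edge flows.  A synthetic-data generator
    emulates the whole survey process for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
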