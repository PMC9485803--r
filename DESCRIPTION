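Package: iigidyn
Title: Coupled Glucose-Insulin-Glucagon Delay-Differential Modelling of
    Isoglycemic Intravenous Glucose Infusion Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and fits a parsimonious three-state delay
    differential equation model of plasma glucose, insulin and glucagon
    dynamics during the isoglycemic intravenous glucose infusion (IIGI)
    experiment.  Insulin secretion is driven by a glucose dose-response
    that is either a single Hill function or a hysteretic pair of Hill
    functions switching at the glucose-curve maximum; glucagon secretion
    is suppressed exponentially in glucose with distinct suppression and
    recovery constants.  Provides weighted Levenberg-Marquardt parameter
    estimation with assay-CV weights, AICc model comparison, exact
    Mann-Whitney U and Spearman rank tests, per-group parameter summary
    tables, and a synthetic-subject generator (infusion profiles,
    equilibrium-consistent parameters, noisy sampled series) so that the
    whole estimation pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
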