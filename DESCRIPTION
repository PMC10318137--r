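Package: neuroforecast
Title: Neuroforecasting Hit Songs from Neurophysiologic Immersion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting aggregate market outcomes of songs from
    second-by-second neurophysiologic immersion recordings. Derives
    song-level neural statistics (average immersion, peak immersion and
    neurologic retreat) from 1 Hz traces with familiarity filtering and a
    first-minute variant, augments small song-level feature tables by
    sequential conditional synthesis with tree-based donor sampling,
    classifies hits with a super-learner ensemble (logistic ridge,
    k-nearest neighbors, kernel machine, neural network) whose simplex
    weights minimize cross-validated risk, and evaluates classifiers with
    exact binomial tests against a base rate, bootstrap model comparison
    and k-fold overfitting checks. Includes a seeded synthetic-cohort
    generator with an AR(1)-plus-dip-episode trace model so the entire
    pipeline is testable without access to proprietary recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    rpart,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
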