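Package: calvingtime
Title: Absorbing Markov Chain Prediction of Calving-Pen Move Timing from
    Cow Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the optimal time to move a periparturient dairy cow to
    an individual calving pen, and the time to calving once moved, from
    hourly multivariate activity budgets (minutes per hour spent feeding,
    moving, resting and ruminating). Hours are labeled with a dominant
    activity by nearest-reference Mahalanobis distance against per-activity
    mean plus k standard-deviation reference points; the label sequence is
    summarized as a co-occurrence matrix and a row-stochastic transition
    matrix, augmented with an absorbing move-to-pen/calving state, and the
    expected absorption time is obtained from the fundamental matrix
    N = (I - Q)^-1. Includes a Monte Carlo absorption simulator used as an
    independent cross-check and a synthetic behavior-series generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
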