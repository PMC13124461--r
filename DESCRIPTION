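Package: winpred
Title: Win-Loss Probability Prediction Under the Proportional
    Win-Fractions Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression tools for prioritized composite time-to-event
    outcomes (death over a nonfatal event). Fits the proportional
    win-fractions (PW) model for the covariate-specific win ratio by
    solving its U-statistic estimating equation, couples it with a Cox
    proportional-hazards model for the time to first event, and combines
    the two to predict absolute, time-dependent win, loss and tie
    probabilities for any pair of covariate profiles. Standard errors are
    obtained from estimated influence functions (robust sandwich form),
    with logit-transformed confidence intervals for probabilities and
    arctanh-based intervals for the net benefit and win odds. Includes
    subject-level win residuals and cumulative score-process diagnostics,
    optional stratification, a Gumbel-Hougaard copula simulator with
    closed-form true win-loss probabilities, and an
    operating-characteristics study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
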