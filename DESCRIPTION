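Package: zflag
Title: Weighted Prediction and Self-Calibrated Flagging of Extreme Random
    Effects in Generalized Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting extreme cluster-level random effects from
    canonical-link generalized linear mixed models with binary or count
    outcomes, and for flagging extreme clusters with controlled error rates.
    Implements weighted random-effect predictors that shrink less than the
    posterior-mean best predictor, exact quadrature-based evaluation of the
    mean square error of prediction conditional on the random effect being
    extreme, exact incorrect and correct flagging probabilities, and
    self-calibration of the weighting parameter so that the simple rule
    "flag when the predicted effect exceeds a threshold" keeps the incorrect
    flagging rate below a nominal level. Includes scenario-grid evaluation
    engines, a clustered-data simulator, and an end-to-end train/validate
    example workflow on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    lme4,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
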