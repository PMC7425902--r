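Package: riskdefaults
Title: Endogenous Default Options in Risky Choice: Simulation, Inference,
    and the Fixed-Point Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying endogenous default options in binary risky
    choice. Implements a softmax expected-utility choice model with
    sign-preserving power utility, MAP parameter estimation with a Laplace
    posterior approximation, analytic model inversion for generating lottery
    sets with a prescribed expected safe-choice probability, a synthetic
    experiment simulator covering competing generative hypotheses about
    default options (natural, dominant, learned) with an explicit binary
    response-time mixture, the associated choice analyses (priming proportion
    tests, mixed-effects logistic regression with backward model comparison,
    response-time manipulation check), and a re-implementation of the
    fixed-point property test for binary response-time mixtures (kernel
    density estimation, pairwise crossing points, and a BIC-approximate
    Bayes factor for a common crossing population).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
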