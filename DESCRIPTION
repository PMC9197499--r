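Package: polycat
Title: Computerized Adaptive Testing for Polytomous Questionnaire Item Banks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating computerized adaptive tests
    (CAT) from ordinal questionnaire data. Implements graded response model
    (GRM) and generalized partial credit model (GPCM) response functions and
    Fisher information, marginal maximum likelihood (Bock-Aitkin EM) item
    calibration with AIC/BIC model selection, item-bank screening
    (principal-component loading filter, Kaiser-Meyer-Olkin sampling adequacy,
    eigenvalue-ratio unidimensionality checks, discrimination filtering and
    ordinal logistic-regression differential item functioning scans), an
    adaptive-testing engine with expected a posteriori (EAP) scoring,
    maximum-information item selection and standard-error stop rules, a
    post-hoc (real-data) cohort simulator, an evaluation harness comparing CAT
    against fixed-length short forms, and a synthetic-data generator for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
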