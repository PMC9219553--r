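Package: hptaxis
Title: Minimal Nonlinear Models of Hypothalamic-Pituitary-Thyroid Axis Regulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A family of minimal parametrized nonlinear ordinary
    differential equation models of hormone regulation in the
    hypothalamic-pituitary-thyroid (HPT) axis, covering thirteen network
    variants of feedforward/feedback coupling between TRH, TSH, FT4 and
    FT3.  Provides right-hand-side and analytic Jacobian evaluation,
    stiff time integration to steady state, a damped positivity-projected
    Newton equilibrium solver cross-checked against closed-form and
    polynomial-root solutions, natural-parameter equilibrium continuation
    with eigenvalue stability assessment and homeostasis classification,
    scenario experiments (hypothyroid onset, non-thyroidal illness,
    exogenous hormone administration, seasonality, peripheral T4-to-T3
    conversion), a seedable synthetic cohort generator, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
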