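Package: t2dsim
Title: Multi-Timescale Simulation of Obesity-Driven Type 2 Diabetes Onset and
    Remission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physiology-based dynamical model of the progression of type 2
    diabetes with weight gain and its remission through weight loss. An
    eight-variable stiff ODE system couples body weight, fasting plasma
    glucose, insulin and free fatty acids, systemic inflammation, peripheral
    insulin sensitivity, and beta-cell mass and function over a timescale of
    months to decades. The package simulates piecewise-constant daily
    energy-intake interventions, computes equilibria and the saddle-node
    bifurcation structure of the BMI-clamped subsystem together with the
    separatrix (unstable-branch) threshold, maps the calorie restriction
    required for remission over the BMI/beta-cell-mass plane, generates
    virtual-patient Monte Carlo cohorts with group statistics, and fits
    selected parameters to sparse time-series observations by weighted
    least squares with Fisher-information asymptotic confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
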