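Package: heelpad
Title: In Vivo Heel-Pad Viscoelastic Property Estimation from Gait Loading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the structural and viscoelastic material properties of
    the human heel fat pad from stance-phase loading data: heel-pad thickness
    from the geometry of a calcaneus point cloud relative to a force-plate
    plane defined by three marker-ball centers, compressive strain and stress
    channels, strain rate as the tangent of the strain-time curve, a nonlinear
    Kelvin-Voigt fit (sigma = E*epsilon + eta*epsilon*epsilon_dot) by
    unconstrained least squares, and the energy dissipation rate of the
    stress-strain hysteresis loop. Includes a calibrated synthetic-cohort
    generator that simulates paired time-zero and post-loading gait trials
    (including rendered 3D scenes exercising the geometry stage end to end),
    plus a cohort statistics layer with median/range summaries, Pearson
    correlation matrices, and paired Wilcoxon comparisons, and a small
    simulate/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
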