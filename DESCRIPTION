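Package: myovib
Title: Vibration-Based Muscle Stiffness and Integrated EMG Analysis of
    Venous Congestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for myotonometry-style
    assessment of venous congestion from skin-mounted accelerometer and
    surface EMG recordings. Generates synthetic experiments in which a
    vibrating unit excites soft tissue modelled as an underdamped
    mass-spring-damper whose stiffness rises over congestion stages,
    extracts windowed muscle stiffness (band-pass filtering, double
    integration to deformation depth, m * a_max / delta_l) and integrated
    EMG features, forms baseline-subtracted deltas, and reproduces the
    stage-wise nonparametric comparison design (exact Mann-Whitney U,
    Lilliefors-style Kolmogorov-Smirnov screen, box-plot summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    nortest,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
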