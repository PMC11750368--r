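Package: antsim
Title: Embodied Ant Navigation Simulation with Kinematic Hexapod Gait Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physics-engine-free simulator for studying embodied insect
    navigation with a kinematic hexapod ant. Provides a jointed ant body
    (legs, antennae, neck, abdomen) with forward and inverse kinematics,
    tripod/ripple/wave gait generation with yaw control, stance-foot
    odometry replacing rigid-body dynamics, synthetic visual worlds
    (panoramic and binocular silhouette rendering), odour trails and a
    filament-based odour plume with coloured-noise wind, and five
    closed-loop navigation controllers: central-complex path integration,
    visual beaconing, a Zernike-moment visual compass, bilateral odour
    trail following, and odour plume tracking. Scenario runners reproduce
    classic desert-ant navigation experiments as deterministic, seeded
    simulations with tidy trajectory logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    optparse,
    withr
Config/testthat/edition: 3
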