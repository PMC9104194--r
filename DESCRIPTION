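Package: maglevneb
Title: Magneto-Archimedes Levitation Fingerprinting of Nanoparticle Protein Coronas
Version: 0.1.0
Authors@R: person("MagLev", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for magnetic levitation (MagLev)
    nanoparticle-enabled blood tests. Models the magneto-Archimedes force
    balance of corona-coated graphene oxide particles in a paramagnetic
    dysprosium(III) nitrate medium, simulates overdamped particle migration
    and synthetic time-lapse levitation imagery, extracts the two MagLev
    fingerprints (starting position and levitating fraction area) from
    vertical intensity profiles, and classifies donor cohorts with Fisher
    linear discriminant analysis, diagnostic metrics, Student's t-test
    heatmaps, confidence ellipses and blind validation. Includes synthetic
    cohort generators and a small-angle X-ray scattering power-law
    (mass fractal dimension) fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
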