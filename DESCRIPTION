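Package: flashchem
Title: Pulsed Ultra-High Dose Rate Water Radiolysis Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the homogeneous chemistry of water radiolysis under
    pulsed ultra-high dose rate (FLASH-regime) electron irradiation. Provides
    a validated reaction-network container with atom and charge balance
    checking, a stiff ODE kinetics engine driven by rectangular pulse trains
    or instantaneous dose deposits, G-value bookkeeping normalized to the
    full pulse energy, chord-based electron source sampling on a micron-scale
    spherical target from a joint energy-direction fluence distribution,
    fluence/dose consistency checks, and synthetic fixture generators so the
    whole pipeline runs without any external Monte Carlo input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
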