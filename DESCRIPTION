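Package: eyedisc
Title: Spatio-Temporal Modelling of Drosophila Eye Disc Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled patterning and growth of the Drosophila
    eye imaginal disc. A five-species signalling network (Hedgehog,
    Decapentaplegic, pMad, Eyes absent, Homothorax) is solved as
    advection-reaction-diffusion equations on a growing two-dimensional
    elliptical domain with finite elements and a moving (arbitrary
    Lagrangian-Eulerian) mesh. Threshold rules on Homothorax and Hedgehog
    classify tissue into progenitor, morphogenetic-furrow and
    differentiated cells; tissue growth is modelled as a Newtonian fluid
    with a proliferation source restricted to progenitors. The package
    also implements FRAP-based parameter estimation (bleach-chase
    degradation rates and confocal-FRAP diffusion coefficients),
    morphogenetic-furrow kinetics, gradient-scaling analysis, parameter
    sensitivity sweeps, model calibration against expression profiles,
    and synthetic-data generators with known ground truth for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
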