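Package: hydrashell
Title: Structural, Orientational and Kinetic Analysis of Ion Hydration Shells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for the first hydration shell of monoatomic
    ions in water. Computes radial structure (ion-oxygen pair distribution,
    shell location, coordination number, translational order), hydrogen-bond
    statistics under the Luzar-Chandler criterion, the geodesic pair
    distribution on the shell sphere together with its bond-orientational
    entropy and a Thomson-problem reference solver, residence-time kinetics
    with stretched-exponential fits, shell-conditioned diffusion, pairwise
    Lennard-Jones plus Coulomb energetics, and charge-distance phase-map
    constructions (susceptibility, structural transformation line,
    hydrogen-bond crossover length, ratio contours). A built-in Metropolis
    Monte Carlo simulator of radially tethered point dipoles around a
    central charge, plus deterministic geometric fixtures, provides
    synthetic shell configurations at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
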