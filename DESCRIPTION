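Package: npcflux
Title: Pore Dilation and Molecular Transport Through the Nuclear Pore Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how dilation of the nuclear pore complex (NPC)
    changes molecular transport. Implements a polymer-scaling model relating pore
    diameter, cargo diameter and transport rate through the correlation (mesh) size
    of the FG-nucleoporin meshwork, together with a coarse-grained Brownian-dynamics
    simulator of the pore: bead-spring FG-Nup chains with sticker-spacer kinetic
    Monte Carlo binding, a rigid spherical cargo with translational and rotational
    Brownian motion, and forward flux sampling of the rare pore-traversal event.
    Includes structural diagnostics (Flory exponent, in-pore mesh size scaling),
    regression of the model's barrier coefficient from simulated rates, and
    reproducible reduced-scale test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
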