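Package: helixatmos
Title: Ion Atmospheres, Hydration, Entropy and Free-Energy Surfaces for
    Parallel DNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for cation-mediated DNA-DNA attraction in
    molecular simulations of parallel duplex pairs. Computes ion-atmosphere
    number and charge density fields, cylindrical concentration profiles and
    excess condensed-counterion integrals, surface-shell charge and
    shell-restricted Coulomb electrostatics (stored interhelical energy along
    a condensation path), hydration-structure metrics (tetrahedral order
    parameter, bound waters, geometric hydrogen bonds), two-phase
    thermodynamics (2PT) and quasi-harmonic macromolecule entropy
    decompositions from velocity densities of states, and reconstruction of
    two-dimensional well-tempered metadynamics free-energy surfaces over
    interhelical distance and azimuthal angle. Includes a synthetic-data
    module that builds idealized B-form duplex pairs, ion and water
    placements with known ground truth, Maxwell-Boltzmann velocities, and toy
    Langevin well-tempered metadynamics runs, so the full pipeline is
    testable without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
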