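Package: gelsim
Title: Coarse-Grained Simulation and Rheology of Multi-Component Colloidal Gel Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained molecular-dynamics model of self-assembling
    colloidal gel networks built from one or two particle species (e.g. a
    semiflexible polymer network combined with a supramolecular fiber
    former). Implements a two-body plus three-body angular energy function
    with per-species and cross-species parameters, Nose-Hoover thermostatted
    randomization, zero-temperature damped quenches to inherent structures,
    single-component and two-component (simultaneous or sequential,
    tether-restrained) gel preparation protocols, Lees-Edwards oscillatory
    shear with an optimally windowed chirp to extract storage and loss
    moduli, start-up-shear differential-modulus (strain-stiffening) curves
    from the virial stress, and two pore-size-distribution estimators for
    particle packings. Includes extended-XYZ and LAMMPS-dump text I/O,
    scenario files, deterministic fixture generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
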