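Package: EncounterMD
Title: Encounter and Binding Analysis for Multi-Copy Protein Molecular
    Dynamics Trajectories
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of protein-protein encounter and binding in
    multi-copy molecular dynamics trajectories. Provides heavy-atom
    contact counting and per-residue contact-frequency profiles,
    center-of-mass distance and optimal-superposition orientation-angle
    time series under periodic boundary conditions, molecular dipole
    moments and scalar dipole-dipole interaction energies and forces in
    a dielectric continuum, translational diffusion coefficients from
    mean-squared displacement, Arrhenius barrier-to-timescale
    conversion, principal-component conformational landscapes of
    C-alpha coordinates with binned log-probability surfaces, binding
    and dissociation event detection, and oligomer-state classification
    from inter-chain contact graphs. Includes a rigid-body Brownian
    trajectory generator with scripted binding events and known ground
    truth so every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'EncounterMD-package.R'
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'topology-methods.R'
    'trajectory-methods.R'
    'io.R'
    'geometry.R'
    'diffusion.R'
    'contacts.R'
    'electrostatics.R'
    'landscape.R'
    'events.R'
    'synthetic.R'
    'pipeline.R'
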