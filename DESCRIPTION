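Package: mpet6
Title: Six-Compartment Multiple-Network Poroelastic Modelling of Perfused Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element solver for a six-compartment multiple-network
    poroelastic (MPET) description of perfused brain tissue: one linear-elastic
    displacement field coupled to six Darcy pore-pressure networks (arterial,
    capillary, CSF/ECF, venous, glymphatic/perivascular, glial) exchanging fluid
    through pressure-driven intercompartmental transfer. Includes generators for
    idealised brain-like geometries (column, annulus, spherical shell) with
    skull/ventricle boundary tags and grey/white tissue partition, pulsatile
    arterial inflow waveform synthesis, physiological boundary conditions
    including a Poiseuille aqueduct coupling, cycle-to-cycle periodic
    steady-state control, derivative biomarker fields (perfusion, CSF/ECF
    clearance, paravenous filtration, compartmental swelling/drainage,
    periventricular fluid content), and an analytic/manufactured-solution
    verification harness (Terzaghi consolidation, convergence studies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
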