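Package: nanoqnar
Title: Atomistic Nanodescriptors and kNN Read-Across Modelling of
    Metal-Oxide Nanoparticle Cytotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds relaxed spherical metal-oxide nanoparticles from bulk
    crystal structures (supercell replication, spherical carving,
    electroneutralisation and Polak-Ribiere conjugate-gradient energy
    minimisation under a Buckingham plus Wolf-summed Coulomb force field),
    computes a 62-column core/shell atomistic nanodescriptor set
    (composition, potential energy, coordination topology, lattice energy,
    size and force-vector statistics including the surface-normal force
    component), and trains and validates a k-nearest-neighbour read-across
    model for percent cell viability with correlation-based feature
    selection, Tropsha external-validation statistics, Y-randomisation and
    an applicability-domain reliability flag.  A batch prediction interface
    accepts JSON or CSV requests and emits the corresponding structured
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
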