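Package: frdex
Title: Fragment-Diabatization Excitonic Modelling of Circular Dichroism in
    Stacked Nucleobase Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and diagonalizes excitonic Hamiltonians with explicit
    charge-transfer (CT) basis states for closely stacked multichromophore
    systems, with DNA G-quadruplexes as the flagship case. Local-excitation
    and CT energies and couplings are obtained by fragment diabatization
    (Loewdin symmetric orthogonalization) of supramolecular-complex adiabatic
    data; a Frenkel/Coulombic baseline, origin-independent velocity-gauge
    rotational strengths, Gaussian-broadened electronic circular dichroism
    spectra, snapshot averaging, stacking-geometry descriptors (overlap
    areas, centre-of-mass distances) and excitonic-state composition
    analyses are included. A synthetic parametrization generator emulates
    the upstream quantum-chemistry step so the whole pipeline is verifiable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    grDevices,
    tools,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
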