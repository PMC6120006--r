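Package: cgrb
Title: Coarse-Grained Rigid-Blob Molecular Dynamics with Multipolar Force Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Coarse-grained rigid-blob (CGRB) simulation toolkit. Expands any
    atom-atom pair potential (Morse, Lennard-Jones) into a series of radial
    coefficients times orientation-dependent angular parts built from
    interaction moment tensors of each rigid molecule, so that inter-molecular
    energies, forces and torques can be evaluated from a handful of tensors
    instead of all atom pairs. Includes a truncated-icosahedron C60 builder,
    Morse-potential fitting of effective single-site interactions, a
    rigid-body NVT molecular dynamics engine (leapfrog translation,
    quaternion/Euler rotation, velocity-rescaling thermostat, periodic
    boundaries) for both the all-atom-summation and coarse-grained engines,
    and liquid-state analysis: radial distribution functions, velocity
    autocorrelation functions and Green-Kubo self-diffusion coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
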