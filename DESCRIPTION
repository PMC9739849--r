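Package: pmmvib
Title: Vibronic Absorption and Emission Spectra from MD Ensembles via the
    Perturbed Matrix Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models vibronic absorption and emission spectra of a chromophore
    embedded in a classical point-charge environment. Per-frame perturbed
    electronic Hamiltonians are built from environment electrostatics in the
    basis of gas-phase electronic eigenstates (perturbed matrix method),
    diagonalized, and assigned to unperturbed states; vibrational structure is
    added through a simplified multi-mode Franck-Condon treatment that
    factorizes overlaps into single-mode integrals for displaced, otherwise
    identical harmonic modes. Includes normal-mode analysis with Eckart
    projection, quantum/semiclassical mode partitioning, Duschinsky diagonality
    checks, threshold-pruned enumeration of vibronic transitions, Gaussian
    line broadening, sub-ensemble statistics, and seeded synthetic generators
    for toy chromophores and solvent-like charge environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
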