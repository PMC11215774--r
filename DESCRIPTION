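Package: csfrohf
Title: Configuration-State-Function Restricted Open-Shell Hartree-Fock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spin-adapted restricted open-shell Hartree-Fock (ROHF) for an
    arbitrary genealogical spin-coupling pattern of the unpaired electrons.
    Builds the configuration state function (CSF) for a +/- coupling path,
    derives the vector-coupling coefficients of the Edwards-Zerner energy
    expression from genealogical coupling matrix elements, assembles the
    per-shell Fock operators, and drives a DIIS/maximum-overlap SCF that can
    hold non-Aufbau (non-Hund) solutions. Ships interchangeable integral
    backends (FCIDUMP files, built-in s-type Gaussian evaluation over XYZ
    geometries, model Hamiltonians such as Hubbard chains) and a dense
    determinant-basis CI in small active spaces used both as a validation
    oracle and for CSF-weight analysis of correlated wave functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
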