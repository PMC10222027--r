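Package: voaconf
Title: Conformational Distributions of Flexible Glycosides from Vibrational Optical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting conformational distributions of flexible
    glycosides (phenyl beta-D-glucopyranoside, gastrodin and relatives) from
    vibrational spectroscopy. Classifies conformers by torsion-angle rotamer
    labels (G+/G-/T, g+/g-/t) and clockwise/counter-clockwise hydroxyl
    OH...O contact networks, converts relative free energies to Boltzmann
    percentage populations, simulates ensemble IR, VCD, Raman and ROA
    spectra by Lorentzian broadening of per-conformer stick spectra with
    linear frequency scaling, refines conformer weights against an
    experimental spectrum by simplex-constrained optimization with a
    Boltzmann prior, and reports grouped conformational abundances such as
    the hydroxymethyl G+:G-:T distribution. Includes a seeded synthetic-data
    generator so the whole pipeline is testable without quantum chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
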