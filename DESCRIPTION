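Package: gquadms
Title: Native ESI-MS Analysis of G-Quadruplex-Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative workflow for native electrospray-ionization mass
    spectrometry of G-quadruplex-ligand complexes: oligonucleotide elemental
    composition and mass arithmetic, theoretical m/z of multiply charged
    complex ions with ammonium and counter-ion adducts, peak-list matching
    and per-stoichiometry area aggregation, fraction-of-bound-quadruplex and
    sequential (1:1, 1:2) equilibrium association constants K1/K2 with
    mass-balance closure, UV-melting Tm/delta-Tm extraction, and a seeded
    synthetic-data generator for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
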