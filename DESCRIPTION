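Package: obpfluor
Title: Fluorescence Characterization of Odorant-Binding Protein Stability and
    Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for steady-state and time-resolved fluorescence
    characterization of lipocalin ligand-binding proteins: exact
    ligand-depletion binding isotherms and dissociation-constant estimation
    from direct-ligand, donor-quench and acceptor-enhancement channels;
    two-state chemical-denaturation fitting with linear baselines and
    linear-extrapolation thermodynamics; Forster resonance energy transfer
    analysis (efficiency, overlap integral, Forster radius, donor-acceptor
    distance, orientation-factor inversion, comparative quantum yield);
    multi-exponential fluorescence-decay fitting by iterative reconvolution
    against a measured instrument response; sigmoidal pH-transition analysis;
    and seeded synthetic-data generators emulating each measurement type.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
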