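Package: korbias
Title: Conformational States, Ligand Bias and Spectral Analysis for Kappa
    Opioid Receptor Signaling Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for biased-signaling studies of the kappa
    opioid receptor (KOR) and related class-A GPCRs. Classifies molecular
    dynamics trajectory frames into six intracellular conformational states
    from the TM3-TM7 distance/dihedral landscape and the R3.50 rotamer,
    computes state population tables and ligand-residue contact
    fingerprints, fits four-parameter logistic concentration-response
    curves from NanoBiT luminescence assays and quantifies ligand bias as
    delta-delta-log(Emax/EC50) with one-sample t-tests, analyses one-site
    saturation and Cheng-Prusoff competition radioligand binding, builds
    ATR-FTIR ligand-exchange difference spectra with band-peak detection,
    and superposes structure models for backbone RMSD and named-atom
    distance measurements. A seeded synthetic-data module generates
    trajectories, assay tables, binding isotherms and spectra with known
    ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
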