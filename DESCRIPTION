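Package: covchar
Title: Quantitative Characterization of Covalent Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for in vitro and cellular characterization of
    covalent small-molecule ligands. Implements competitive fluorescence
    polarization (FP) kinetics for two-step covalent inhibition (per
    concentration k_obs by early-window linearization, saturation and
    linear-regime fits for k_inact, K_I and the covalent efficiency
    k_inact/K_I, and the reversible K_i at time zero), exact one-site
    equilibrium binding with ligand depletion for probe K_L and competition
    IC50 with conversion to K_i, thermal-shift analysis for DSF (first
    derivative melting temperature) and split-NanoLuc CETSA (percent
    stabilized normalization, Boltzmann T_agg, dose-response EC50 of the
    T_agg shift), glutathione-reactivity half-life by pseudo-first-order
    decay, binding thermodynamics and ligand-efficiency arithmetic, and
    signed elemental-composition parsing with monoisotopic and average mass
    computation for covalent adducts. A seeded synthetic-data module
    generates plate-reader style CSV datasets with known ground truth for
    every assay layout so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
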