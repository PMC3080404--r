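Package: flexscan
Title: Conformational Flexibility Analysis of Protein Structure Ensembles
    and Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying conformational flexibility of a protein
    from crystallographic ensembles and molecular dynamics trajectories:
    iterative least-squares ensemble superposition (Kabsch rotations) with
    per-residue C-alpha RMSD-to-mean profiles, crystallographic and
    trajectory-derived B-factor profiles with zero-mean/unit-variance
    normalization, mass-weighted quasiharmonic principal component analysis
    with 2kT extreme-conformation projection, and Shrake-Rupley solvent
    accessible surface area with fractional side-chain accessibility against
    an extended Gly-X-Gly reference state. Includes seeded synthetic-data
    generators (planted-amplitude ensembles, planted-mode Gaussian
    trajectories) and a config-driven reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
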