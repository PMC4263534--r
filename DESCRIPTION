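Package: atomstress
Title: Atomic-Resolution Virial Stress Analysis of Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-atom virial stresses (mean principal stress and
    hydrostatic pressure) from classical molecular-dynamics trajectories,
    decomposed by force-field term: bond stretch, angle bend, torsion,
    Coulomb, van der Waals, generalized-Born (OBC) implicit solvent, and
    kinetic contributions. Many-body angle and torsion gradients are
    decomposed into central pairwise forces so that every contribution can
    be attributed to an atom pair. Includes residue-level averaging with
    fluctuation and autocorrelation-corrected standard-error statistics,
    PDB B-factor outputs for visualization, a portable text topology and
    trajectory format, a graphene ribbon/nanotube builder with a minimal
    NVE integrator for stress-wave experiments, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
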