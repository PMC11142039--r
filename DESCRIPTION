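Package: chargebem
Title: Charge-Based Boundary-Element EEG Forward Modeling with Adaptive
    Mesh Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates scalp EEG from current dipoles in nested-shell head
    phantoms using the charge-based formulation of the boundary element
    method (BEM), with adaptive mesh refinement (AMR) driven by the
    per-facet total charge magnitude and an electrode-voltage stopping
    rule.  Includes a semi-analytic multilayer concentric-sphere oracle
    for forward-solution validation (RDM/MAG metrics), triangle-mesh
    generation and STL/PLY/OFF input/output, 5-layer and 3-layer
    conductivity presets, deterministic electrode layouts, single-dipole
    source reconstruction (lead fields, residual-variance grid search and
    Nelder-Mead refinement), and a study driver comparing 5-layer forward
    models against 3-layer inverse models with and without AMR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
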