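Package: erpsource
Title: Cortical Source Analysis of Infant ERP Components with
    Conductivity-Based Head Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for cortical source analysis
    of infant event-related potentials (ERPs). Generates synthetic cohorts
    of layered head geometries, region-of-interest atlases, electrode
    montages and four-condition ERP averages; builds conductivity-annotated
    four-shell head models with analytic Legendre-series lead fields;
    constructs average head-model templates by iterative alignment and
    averaging with an RMS-difference stopping rule; detects P1-anchored
    N290 peaks; reconstructs current density with eLORETA and summarizes it
    per region of interest; and compares substitute head models against
    subject-specific ones with difference scores, Pearson correlations,
    mixed-design ANOVA and a head-model ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
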