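Package: allopocket
Title: Cryptic-Pocket Trajectory Classification and Allosteric Ternary
    Complex Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two linked analyses of muscarinic acetylcholine
    receptor (mAChR) allosteric pharmacology. First, a per-frame classifier
    of a cryptic extracellular-vestibule pocket in molecular dynamics
    trajectories: Ballesteros-Weinstein residue addressing against a PDB
    topology, minimum heavy-atom distance metrics, subtype-specific
    open/closed rules at a 5 Angstrom threshold, moving-average smoothing,
    open-fraction summaries and distance histograms. Second, the allosteric
    ternary complex model for radioligand interaction binding: forward
    prediction, global shared-parameter nonlinear least-squares fitting on
    log-scale parameters, cooperativity-adjusted affinities with propagated
    standard errors, and wild-type versus mutant comparison by one-way
    ANOVA with Dunnett's post hoc test. A synthetic-data module generates
    two-state Markov pocket trajectories and binding curves with known
    parameters so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    multcomp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
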