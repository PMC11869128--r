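Package: mfbo
Title: Multifidelity Bayesian Optimization for Molecular Discovery
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batched multifidelity Bayesian optimization (MF-BO) for
    discrete molecular libraries screened at assays of different cost and
    quality (docking-like scores, single-point percent inhibition,
    dose-response pIC50).  Provides a Gaussian-process surrogate with a
    Tanimoto kernel on Morgan fingerprints and an intrinsic
    coregionalization structure across fidelities, cost-aware expected
    improvement with Monte-Carlo fantasy batch selection under a budget, a
    Hill-equation assay simulator with decoy injection, tools to build
    libraries with controlled diversity and interfidelity correlation, a
    retrospective campaign benchmark against funnel, transfer-learning,
    single-fidelity-BO and random baselines, and a reaction-template
    genetic molecule generator with non-dominated sorting.  Chemistry
    primitives (SMILES, fingerprints, substructure filters, reaction
    templates) are delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with rdkit, on the PATH as 'python'
    or 'python3'.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
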