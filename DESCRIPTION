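Package: DisorderBench
Title: Site-Specific Protein Disorder from NMR Ensembles and Benchmarking of
    Disorder Predictors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies site-specific protein disorder from multi-model NMR
    structure ensembles through two per-residue order parameters: a circular
    (dihedral-angle) order parameter S and a superposition-free coordinate
    order parameter T derived from the inter-atomic variance matrix of
    Calpha distances. Benchmarks per-residue disorder predictors against
    continuous chemical-shift-derived Z-scores using Pearson and Spearman
    correlation, ROC/AUC, Matthews correlation, and a bias/discrimination
    decomposition of predicted probabilities (pZL, pZH, pZA, pZD), and
    compares conditional Z-score distributions with the Jensen-Shannon
    divergence. Includes readers for multi-model PDB ensembles, REMARK 465
    missing-residue labels, Z-score and predictor tables, and a fully
    seeded synthetic-data generator (bimodal Z-score profiles, predictors
    with planted bias and discrimination, conformer ensembles with planted
    disorder) so that the whole analysis is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'io-pdb.R'
    'io-tables.R'
    'io-report.R'
    'order-dihedral.R'
    'order-coordinate.R'
    'order-profile.R'
    'transforms.R'
    'metrics-pairing.R'
    'metrics-correlation.R'
    'metrics-classification.R'
    'metrics-bias.R'
    'metrics-ranking.R'
    'divergence.R'
    'synthetic.R'
    'pipeline.R'
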