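Package: idpr2
Title: Sequence-Based Prediction of Backbone Amide R2 Rates for
    Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts per-residue backbone amide 15N transverse relaxation
    rates (R2) of intrinsically disordered proteins from sequence alone.
    The model expresses R2 of each residue as the product of Lorentzian
    contributing factors from all residues of the chain, governed by 20
    amino-acid propensity parameters and one sequence-distance coefficient,
    with a single uniform scale factor per protein. Includes nonlinear
    least-squares training with positivity bounds, leave-one-out and k-fold
    cross-validation, null and one-residue baselines, a correlation-length
    sweep, a helix-boost correction driven by secondary-structure
    propensity scores, a synthetic-data generator with known ground truth,
    and readers/writers for FASTA, per-residue R2 tables, ss2 files,
    parameter files and dataset manifests.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
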