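Package: sicnv
Title: Spatially Inferred Copy Number Variation from Barcoded Spot Transcriptomes
Version: 0.1.0
Authors@R:
    person("sicnv", "developers", email = "sicnv@example.org", role = c("aut", "cre"))
Description: Infers genome-wide copy-number profiles (siCNVs) from spatially
    barcoded spot transcriptomes (10x Visium-style UMI count matrices).
    Expression is ordered along the genome, centred on a benign reference set,
    smoothed with a pyramidal moving average and segmented into six discrete
    copy states with a hidden Markov model. Spots are grouped into clones by
    hierarchical clustering of their residual profiles, clone phylogenies are
    built from shared copy-number events under a no-reversal assumption (with
    branch lengths and clone diameters on a logarithmic scale), and a
    maximum-parsimony alternative is provided. A built-in agent-based tissue
    simulator generates spatially structured clonal populations with known
    copy numbers so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    ape,
    phangorn,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
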