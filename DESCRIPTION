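Package: stconnectome
Title: Spatiotemporal Connectome Analysis of Developmental Brain Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds structurally constrained multilayer coactivation graphs
    (spatiotemporal connectomes) from region-wise BOLD fMRI time series and a
    binary structural-connectivity template, extracts their weakly connected
    components, and quantifies each component's System Diversity (entropy of
    functional-system recruitment) and the Spatiotemporal Diversity of the
    component repertoire (mean pairwise cosine similarity of activation maps)
    at global, functional-system, and nodal scales. Includes framewise
    displacement / DVARS motion scrubbing of components, CC-reassignment
    permutation tests with Benjamini-Hochberg correction, edge-length and
    inter-system usage analyses against age, and a synthetic-cohort generator
    with planted, parameterized developmental effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
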