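Package: mplexfdr
Title: FDR-Bounded Perturbed Subnetwork Detection on Multiplex PPI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects significantly perturbed gene subnetworks jointly supported
    by several protein-protein interaction (PPI) networks. Input networks are
    modelled as layers of a multiplex network sharing one set of physical gene
    nodes; per-gene p-values (e.g. from MutSig2CV) are converted to local false
    discovery rates by an empirical Bayes two-groups fit. Around each
    low-lfdr seed gene, a local graph is extracted with an approximate
    personalized PageRank push on the classic multiplex random walk, and the
    connected, layer-covering subnetwork of minimum random-walk conductance
    whose mean local FDR stays below a user bound is found by Dinkelbach
    iteration over mixed-integer linear programs. Includes a planted-module
    simulation benchmark with signal-to-noise p-value generation,
    degree-preserving network randomization, and F / symmetric-Fsub / exact-FDR
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
SystemRequirements: Python (>= 3.8) with scipy >= 1.9 on the PATH (MILP
    backend via the bundled helper script).
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
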