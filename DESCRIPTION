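Package: boolgap
Title: Minimum Reaction Insertion for Boolean Metabolic Network Gap Filling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Gap filling of metabolic networks in a Boolean (AND-OR) model.
    Given a host metabolic network embedded in a larger reference network, a
    set of seed (source) compounds and a target compound, the package finds a
    minimum-cardinality set of reference reactions whose insertion makes the
    target producible under least-fixpoint (minimal valid assignment)
    semantics.  Producibility is decided by the unique minimal valid
    assignment, which excludes self-sustaining cycles that are not connected
    to any source.  The search is encoded as a binary integer linear program;
    a feedback-vertex-set decomposition with node splitting keeps the number
    of time-expanded variables small, and an exact branch-and-bound solver
    with constraint propagation is included.  Utilities cover KEGG KGML
    pathway parsing, reversible-reaction decomposition, a vertex-cover
    reduction with degree-bounding gadgets, deterministic fixtures and a
    seeded random-instance generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
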