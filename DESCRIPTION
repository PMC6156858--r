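Package: acidoscreen
Title: Drug-Screen Normalization, GO Enrichment and Community Summaries for
    Acidosis-Adapted Cancer Cell Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for the computational stages of a
    plate-based drug screen on acidosis-adapted cancer cells and its
    transcriptomic follow-up: per-plate percent-inhibition normalization
    with Z-factor quality control and threshold hit calling,
    four-parameter logistic dose-response confirmation with IC50
    selectivity profiles, classic-Fisher Gene Ontology over-representation
    of a differential-expression table, spin-glass Potts-model community
    detection on the induced ontology graph with HITS-authority
    representatives and graph collapse, and expression summaries
    (log-CPM transform, row scaling, top-variance PCA, per-community
    profiles). A synthetic-data generator with planted ground truth
    emulates every input class so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
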