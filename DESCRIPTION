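Package: vagalseq
Title: Projection-Barcode and Multimodal Analysis of Vagal Sensory Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multiplexed projection-barcoded single-cell
    data from vagal sensory neurons together with the companion assays used
    to characterise them. Provides barcode-based organ assignment with
    quality-control and damaged-cell filters, organ-position and tissue-layer
    trajectory scoring on a 2-D embedding, calcium-imaging delta-F/F response
    classification with marker-rule subpopulation calls, landmark-based rigid
    registration between in vivo image stacks and post-hoc tissue sections,
    exhaustive cluster-to-ending-type assignment optimisation, a bipartite
    characteristic-pair correlation index, and brainstem innervation
    profiling with average-linkage trees. A synthetic-data module generates
    every pipeline input with known ground truth so that all stages are
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
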