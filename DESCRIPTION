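Package: dashweave
Title: Programmatic Multi-Page Dashboards for Omics Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Iterative, programmatic construction of multi-page interactive
    dashboards from within omics analysis pipelines. Provides a dashboard
    document model with predefined page layouts, generic content dispatch
    (markdown, images, tables, declarative figures, injected callables),
    document-wide colormaps, a declarative linked-view protocol compiled to
    client-side wiring, and deterministic rendering to a single
    self-contained HTML file. Includes a single-cell RNA-seq extension
    (quality-control metrics, highly variable gene selection via a
    mean-variance trend, marker-gene ranking, linked embedding views) and a
    negative-binomial simulator with planted ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
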