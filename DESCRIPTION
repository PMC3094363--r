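Package: allomenv
Title: Prediction Envelopes for Model-Selection Uncertainty in Live-Tree Carbon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the uncertainty that model selection introduces into
    live-tree carbon estimates. Builds interval prediction envelopes from
    libraries of allometric volume and biomass equations on 1-cm diameter
    classes, aggregates tree components to total-tree carbon over a
    directed-acyclic calculation roadmap under positive or negative
    component-correlation assumptions, scales envelopes to a regional
    inventory with expansion factors, and reports half-range uncertainty,
    species shares, and uncertainty-reduction experiments. Includes an
    asymptotic height-diameter model and synthetic generators for equation
    catalogs, wood-density tables, and inventories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
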