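Package: colonysim
Title: Agent-Based Simulation of Metabolically Heterogeneous Yeast Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lattice agent-based model of a clonal yeast colony in which
    gluconeogenic ("dark") cell blocks budget a non-limiting aspartate flux
    between carbon and nitrogen pools and secrete trehalose into a diffusing
    extracellular field, while glycolytic ("light") cell blocks emerge by
    threshold-triggered stochastic switching and consume that field. Provides
    a seeded simulation engine with an explicit FTCS diffusion solver,
    colony initialization, per-block metabolic and division rules, spatial
    and division-rate metrics, parameter sweeps over the aspartate budgeting
    fraction and uptake ratio, snapshot input/output and colony rendering.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
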