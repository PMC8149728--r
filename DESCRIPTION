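Package: intercom
Title: Functional Cell-Cell Communication Inference from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("InterCom", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers functional, secreted-ligand-mediated cell-cell interactions
    from single-cell RNA-seq count data by integrating extracellular
    ligand-receptor binding events with an intracellular signaling model and
    transcriptional-regulation compatibility testing. Signaling hotspots are
    identified as the high-probability states of a finite discrete Markov chain
    over an expression-weighted signaling network; hotspot-to-transcription-factor
    compatibility is assessed along signed paths with an upper-tail hypergeometric
    test; interactions are scored as the product of mean ligand and receptor
    expression over expressing cells and top-decile scores are flagged
    significant. Includes a seeded synthetic-data generator that plants a
    ligand-receptor-cascade-TF-target signal, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    data.table,
    methods,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
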