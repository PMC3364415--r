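Package: ephemsim
Title: Hierarchical Ephemeral Speciation Simulation and Diversification
    Rate Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven (Gillespie) stochastic simulation of a
    hierarchical model of ephemeral speciation, in which incipient
    lineages arise within full species, are lost by extinction or
    reabsorption, or are promoted to new full species.  Includes a
    constant-rate birth-death baseline sharing the same output types,
    derivation of the species-level tree from the incipient-lineage
    genealogy, tree summary statistics (lineage-through-time curves,
    the gamma statistic, the Colless imbalance index, incipient-form
    histograms, effective per-species rates), and speciation-rate
    estimators (richness-versus-age, waiting-time conversion, Yule and
    birth-death maximum likelihood on branching times).  Trees are
    exchanged as 'ape' "phylo" objects and annotated Newick files; a
    command-line entry point drives batch simulation, summaries and
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
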