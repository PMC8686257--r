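Package: dfgdiff
Title: Process Variant Comparison via Stochastic Directly-Follows Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing process variants (cohorts) recorded in event
    logs. Estimates first-order Markov transition structure by counting
    directly-follows relations between consecutive states within each case
    (a directly-follows graph, DFG), normalises the counts row-wise into
    transition probabilities (a stochastic DFG), and contrasts two cohorts by
    signed probability differences above a cut-off level. Includes event-log
    reading, validation, cohort splitting and stratified case sampling, a
    Markov-chain simulator for generating synthetic two-cohort logs, Graphviz
    DOT emission of process maps and difference maps (negative flows dashed),
    and a command-line interface covering the split-discover-compare workflow.
License: MIT
Encoding: UTF-8
Imports:
    utils,
    stats,
    jsonlite,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
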