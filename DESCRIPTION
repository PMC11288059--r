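Package: chloroscaf
Title: Chloroplast Genome Scaffolding by Exact Integer Linear Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-free scaffolding of chloroplast genome assemblies.
    Orients and orders contigs into a circular sequence of genomic regions
    (direct repeats, inverted repeats and single copies) by solving exact
    integer linear programs over a multiplied doubled contig graph, with a
    flow-based circuit formulation and explicit repeat-order constraints.
    Repeat scaffolding problems are solved in hierarchical succession, the
    solution circuit is decomposed into regions, and all coexisting genome
    forms (structural haplotypes) are enumerated as Eulerian circuits of a
    region graph.  Includes a generator for perfect and noisy artificial
    benchmark instances and polynomial certificate validators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) for the default
    MILP backend (HiGHS via scipy.optimize.milp).
Config/testthat/edition: 3
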