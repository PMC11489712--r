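Package: keylint
Title: Assessment, Linting, and Simulation of Dichotomous Identification Keys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative assessment of dichotomous identification
    keys of the kind that accompany taxonomic descriptions. Parses conventional
    numbered-couplet key text into a formal graph model, computes path-length
    statistics including closed-form bounds for maximally comb-shaped and
    fan-shaped topologies, detects structural and wording defects (leap-frog
    couplets, numbering errors, polychotomies, loops, monothetic couplets,
    uncontrasted or indecisive features, missing retracing and illustration),
    scores keys against a 17-criterion binary suboptimality rubric with
    not-applicable handling, aggregates corpus-level statistics, and generates
    synthetic keys and corpora with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'key-model.R'
    'key-graph.R'
    'parser.R'
    'renderer.R'
    'metrics.R'
    'lint.R'
    'rubric.R'
    'corpus-stats.R'
    'synthetic.R'
    'report.R'
    'cli.R'
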