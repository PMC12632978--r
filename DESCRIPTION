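Package: novoscreen
Title: Combinatorial Cytokine-Mimetic Agonist Screening and Hit Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing combinatorial screens of
    binder-fusion cytokine agonists ("novokines"): all-by-all enumeration of
    two-domain fusion libraries from a receptor-binder registry, a seeded
    synthetic generator of multi-donor phospho-flow screen data built on a
    ternary-complex (receptor bridging) equilibrium model with planted ground
    truth, hit calling by per-stratum 0-1 normalization and a mean + k x SEM
    rule with a donor-reproducibility gate, dose-response classification into
    saturable, non-saturating and no-signal mechanisms, and receptor-knockout
    dependence testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
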