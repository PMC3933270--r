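Package: ontogram
Title: Quantitative Cladistic Analysis of Ontogenetic Growth Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs ontogenetic growth series ("ontograms") from
    morphological growth-character matrices by maximum parsimony. Provides
    NEXUS matrix input/output with character metadata, hypothetical-embryo
    polarization and artificial-adult rooting checks, additive-binary
    recoding of multistate growth characters, heuristic, branch-and-bound
    and exhaustive parsimony searches, strict, semi-strict, Adams and
    majority-rule consensus, ACCTRAN and DELTRAN character optimization
    with synontomorphy extraction, Bremer decay and bootstrap support,
    ensemble and per-category consistency indices, ontogenetic ranking
    with a tied-rank Spearman correlation against a size proxy, and a
    seeded generator of synthetic growth matrices with known maturity
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
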