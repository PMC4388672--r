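Package: isonymia
Title: Surname Isonymy, Distance Trees and Robustness Analysis for
    Double-Surname Census Rosters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study population structure from surname corpora in
    countries with a double-surname system. Parses individual-level census
    rosters into single-surname tokens, applies municipal and global
    frequency cutoffs, and computes isonymy together with Hedrick and Nei
    similarity coefficients and their log-distance transforms. Builds
    neighbor-joining trees from surname distance matrices, assesses their
    robustness by surname-type bootstrap and by noisy clustering of
    externally supplied (e.g. dialectometric) distance matrices, and
    summarises replicates as majority-rule consensus trees with percent
    support. Includes Mantel permutation tests, representativeness
    regressions, percent-agreement linguistic similarity, a synthetic
    roster generator with planted regional structure, and per-province
    summary tables of the 2008 Spanish municipal register packaged as
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    geosphere,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
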