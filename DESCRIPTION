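Package: CanalDyn
Title: Canalizing Depth and Attractor Dynamics of Random Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing canalization in synchronous Boolean
    networks. Provides exact canalizing-depth computation and the unique
    layered (He-Macaulay) decomposition of Boolean functions given as
    truth tables, uniform random generation of Boolean functions and
    networks of prescribed canalizing depth via ordered set partitions,
    exhaustive attractor and basin-of-attraction enumeration on the
    2^n-state space, ensemble summary statistics (number of attractors,
    total and average attractor size) across canalizing depths, and the
    exact transfer-matrix computation of the limiting expected number of
    attractors of each length in large random depth-one networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils-bits.R'
    'AllGenerics.R'
    'AllClasses.R'
    'CanalDyn-package.R'
    'truth-table.R'
    'hm-decomposition.R'
    'sampler.R'
    'dynamics.R'
    'statistics.R'
    'theory.R'
    'io.R'
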