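Package: passentropy
Title: Entropy-Based Variability Metrics for Weighted Directed Passing Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes entropy-based rates, bounded indexes, total entropies and
    transmission-style capacities for weighted directed interaction networks,
    such as the pass networks recorded in team sports. Metrics are derived from
    the row-stochastic Markov transition matrix of the weighted adjacency
    matrix: per-node rates of passing and reception, their [0,1] indexes,
    network-level rates and indexes, marginal (total) out- and in-entropies,
    and passing/reception capacities with two documented reception variants
    (a literal substitution and a conditional-entropy reading that recovers
    mutual information). Includes adjacency-matrix and pass-event CSV
    input/output, a Dirichlet-multinomial synthetic match generator, random-walk
    pass-sequence simulation, ggplot2 charts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
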