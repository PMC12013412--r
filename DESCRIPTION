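Package: entred
Title: Relative-Entropy Measures of Functional Redundancy and
    Interdependency in Microbial Communities
Version: 0.1.0
Authors@R:
    person("entred", "developers", email = "entred@example.org",
           role = c("aut", "cre"))
Description: Quantifies single-trait functional redundancy of functionally
    annotated microbial communities through Kullback-Leibler divergence:
    sample and reference taxon-based redundancy, abundance-based redundancy,
    and a functional interdependency index, all in nats. Includes classical
    alpha-diversity indices, community-level functional redundancy via Rao's
    quadratic entropy with Gower dissimilarity as a contrast, preprocessing
    of per-species maximal secretion-flux tables (sign convention,
    missingness rules, sample and function inclusion filters), a Dirichlet
    synthetic-community simulator quantifying the effect of unclassified
    species, fixture generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
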