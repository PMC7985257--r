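Package: nestweb
Title: Nestedness, Null Models and Specialization for Bipartite
    Plant-Mycorrhizal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bipartite host plant-arbuscular mycorrhizal
    (AM) fungal association networks built from OTU count tables: matrix
    construction (rare-OTU filtering, low-depth sample exclusion, rarefaction,
    per-host aggregation), the NODF nestedness metric with a max-NODF
    optimizer and the connectance-corrected NODFc, permutation null models
    (equiprobable EE, fixed-fixed FF, and a quantitative marginal- and
    fill-preserving swap null) with standardized effect sizes and empirical
    P-values, specialization indices (degree, Kullback-Leibler d', network
    H2'), the checkerboard C-score, alpha diversity and Bray-Curtis host
    dissimilarity, and a tunable synthetic two-site community generator for
    end-to-end testing of urbanization-style contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    picante,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
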