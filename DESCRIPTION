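Package: radhub
Title: Hub-Gene Discovery in Post-Irradiation Bone-Marrow Recovery Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline pipeline for identifying hub genes from short
    expression time courses of recovering bone marrow after ionizing
    radiation. Provides per-timepoint differential calling with
    Benjamini-Hochberg correction, short time-series clustering against
    integer model temporal profiles with exact permutation significance,
    Fisher's exact gene-set enrichment with a GO-term subsumption map,
    Pearson correlation network construction with k-core hub detection,
    literature-overlap seeded protein-protein interaction subnetwork
    extraction, and 2^-ddCt qPCR validation. A seed-deterministic
    synthetic-data generator with planted differential genes, temporal
    profiles, co-expression modules and enriched annotation terms supports
    end-to-end benchmarking with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
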