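Package: grafonet
Title: Mixed Graphical Models via Random-Forest Stability Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers sparse conditional-dependence networks over mixed
    continuous/binary/categorical variables (multi-omics markers and
    clinical phenotypes) using per-variable random-forest importance
    ranking combined with complementary-pairs stability selection for
    family-wise error control. Includes the surrounding analysis layer:
    rank-based pre-processing (missingness filters, imputation,
    inverse-normal transform, indicator coding), network topology
    (centralities, small-world index, modularity-based module
    detection with an exact branch-and-bound solver), robustness
    diagnostics (edge-cutoff sweeps, adjusted Rand comparisons,
    twin-split replication), and a latent-Gaussian generator of
    mixed-type data with known graph structure for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
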