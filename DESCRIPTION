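Package: fdassembly
Title: Functional Diversity Indices and Null-Model Assembly Inference for
    Mixed-Trait Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based community analysis with mixed
    (binary plus continuous) trait tables: Gower dissimilarities with
    pool-level ranging, Cailliez-corrected principal coordinates, UPGMA
    functional dendrograms, and the per-community indices FD (dendrogram
    branch-length sum), FEve (functional evenness on the minimum spanning
    tree), Rao quadratic entropy and the Simpson index, with Jost
    equivalent-number corrections. Observed indices are standardized
    against trait-shuffle null models (standardized effect sizes, SES) to
    infer community assembly processes (niche filtering versus limiting
    similarity), and habitats are contrasted with permutation t tests,
    one-sample assembly tests, Spearman decoupling correlations and
    Moran's I spatial checks. A synthetic two-landscape community
    generator with known assembly rules (neutral, niche filtering,
    limiting similarity) makes every stage of the pipeline testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
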