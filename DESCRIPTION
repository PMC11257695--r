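Package: boolexpr
Title: Linking Single-Cell Expression Pseudocounts and Boolean Gene Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bidirectional bridge between single-cell RNA-seq log-pseudocount
    matrices and Boolean gene-activity states. Learns per-gene distribution
    profiles from a reference matrix of highly variable genes (unimodal,
    bimodal or zero-inflated, via Hartigan's dip test, the bimodality index
    and density-peak location), fits an exponential-decay probabilistic
    dropout model with gene-wise parameters, binarises expression matrices
    into active/inactive/undetermined calls with category-dependent rules,
    and generates synthetic pseudocount data from Boolean network traces by
    biased sampling plus dropout simulation. Includes a small Boolean network
    toolkit (BoolNet-format text parser, synchronous and fully asynchronous
    traces, stable states, signed influence graphs) and a synthetic reference
    generator with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    digest,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
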