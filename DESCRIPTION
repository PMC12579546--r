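Package: darkzsl
Title: Zero-Shot Phosphosite to Dark-Kinase Association Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking zero-shot prediction of the kinases that
    phosphorylate a given phosphosite, aimed at understudied ("dark") kinases.
    Provides leakage-aware train/validation/test split generation with
    kinase-group stratification and sequence-identity clustering, baseline
    sequence encodings (one-hot, BLOSUM62, NLF, ProtVec) and pooling of
    precomputed protein language model embeddings, a training-free
    k-nearest-neighbour zero-shot classifier, a bilinear compatibility model
    trained with regularized cross-entropy, a multilabel ranking evaluation
    suite (macro average precision, family/group/masked-group AP, hit@k,
    Monte-Carlo random baselines), and a synthetic benchmark generator so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
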