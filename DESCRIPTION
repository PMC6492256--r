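Package: morphocomplex
Title: Morphological Conditioning Complexity in Artificial Language Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing miniature artificial-language learning
    experiments in which suffix choice may be conditioned on semantic features
    of the described scene. Provides the complex target language used for
    training, normalized-Levenshtein production scoring with automatic
    stem/suffix segmentation, a model-selection based conditioning-complexity
    statistic (exhaustive multinomial model enumeration over full and
    collapsed semantic predictors, selected by AIC), suffix entropy,
    constructors for mixed multi-speaker training input, a constrained
    generator of small noun-verb languages with irregular cells, a simulator
    of dyadic director-matcher interaction with accommodation, and the
    descriptive and contingency statistics used to summarise such studies.
    A seeded synthetic-data generator emulates learner productions so that
    every pipeline stage can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
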