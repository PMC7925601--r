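Package: speechtrf
Title: Temporal Response Functions for Semantic Processing in Continuous-Speech EEG
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encoding-model analysis of electrophysiological responses to
    continuous speech. Builds word-level lexical-surprisal (interpolated
    modified Kneser-Ney 5-gram) and semantic-dissimilarity (embedding-based)
    regressors, estimates temporal response functions by lagged ridge
    regression with fourfold cross-validation and permutation-null model
    comparison, denoises multi-subject EEG with multiway canonical
    correlation analysis, extracts N400 trough latencies, and applies the
    associated group and partial-correlation statistics. Ships a seeded
    forward-model simulator (synthetic lexicon, corpus, transcript and
    multichannel EEG) so the full pipeline is testable end to end without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
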