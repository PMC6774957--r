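Package: gewmvpa
Title: Classifier-Based Decoding of Colour-Emotion Association Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern classification for colour-emotion
    association ratings collected with the Geneva Emotion Wheel. Quantifies
    the colour-specificity of emotion associations (decoding the rated
    colour term from 20 emotion-intensity ratings), the country-specificity
    of those associations (decoding a participant's country from 240
    ratings, and the in-group advantage of cross-country classifier
    transfer), and inter-colour similarity estimated from decoding
    confusions with Luce's biased-choice model. Provides participant-grouped
    cross-validation with error-correcting output-code support vector
    machines, permutation-null significance testing, a seeded zero-inflated
    ordinal rating simulator, and a configuration-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
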