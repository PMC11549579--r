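Package: peertrends
Type: Package
Title: Emotion Trend Analysis for Moderated Peer-Support Chats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@peertrends.dev",
    role = c("aut", "cre"))
Description: Analysis pipeline for momentary loneliness and optimism in
    timestamped multi-party peer-support chat transcripts. Builds per-message
    scoring contexts from the conversation history, grids per-user emotion
    score series onto a 0-68 minute grid by linear interpolation with
    constant extrapolation, detects the onset of significant change with
    one-sided Mann-Whitney U tests against a 5-minute reference, and compares
    moderator+single-user with moderator+small-group sessions after logistic
    propensity-score matching with a 25-percent-of-SD caliper. A seeded
    synthetic chat-corpus generator with exported latent ground truth makes
    every stage testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
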