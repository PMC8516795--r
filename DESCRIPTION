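Package: gazematch
Title: Consensus-Based Elastic Matching of Recall Fixations onto Encoding Fixations
Version: 0.1.0
Authors@R: person("gazematch", "developers", role = c("aut", "cre"),
    email = "gazematch@example.org")
Description: Tools for the looking-at-nothing paradigm in visual cognition:
    an elastic point-set registration algorithm that relocates recall
    fixations (made on a blank screen while recalling a scene) onto the
    fixations recorded while encoding the scene.  Recall fixations are
    moved by a moving-least-squares field of local rigid transforms fitted
    to Gaussian-consensus targets in the encoding set, then matched within
    a visual-angle radius.  Includes gaze density map construction,
    saliency-style validation metrics (AUC, Pearson correlation),
    a synthetic trial generator with ground-truth correspondence, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
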