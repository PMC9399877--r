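Package: eran
Title: Emotion-Based Reinforcement Attention Networks for Depression
    Detection from Social-Media Post Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies social-media users as depressed or non-depressed
    from their post histories using an emotion-based reinforcement
    attention network (ERAN). A convolutional text classifier pretrained
    on a three-class emotion task supplies per-post emotion vectors; a
    policy-gradient (REINFORCE) agent whose state is augmented with those
    emotion vectors walks each user's posts in order and selects the
    depression-indicator subset; a bidirectional LSTM encodes posts and a
    sentence-level attention layer pools the selected posts before a
    fused softmax classifier. Includes a synthetic-data generator with
    planted indicator posts for end-to-end validation, evaluation
    metrics, ablation variants, a selected/unselected subset experiment,
    and attention-weight export. All networks and their gradients are
    implemented in base R and checked against finite differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
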