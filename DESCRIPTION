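Package: huangnet
Title: Huang-Sized Two-Hidden-Layer Feedforward Classifiers for Behavioral and EEG Component Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized classification of continuous behavioral and
    electrophysiological data with two-hidden-layer feedforward networks whose
    hidden-layer sizes are fixed in closed form from the sample and output
    counts (Huang's construction). Provides the network (tanh hidden layers,
    softmax output, exact backpropagated gradients), full-batch training by
    scaled conjugate gradient or resilient backpropagation with a
    consecutive-correct validation stopping rule, an expert rule system that
    labels joystick trajectories from a virtual T-maze into six behavioral
    categories, feature builders for the 6003-element trajectory vector and
    the 1603-element EEG independent-component vector, seeded synthetic-data
    generators for both problems, and an evaluation battery: thresholded
    category selection with missed-trial counting, one-vs-rest confusion
    counts and metrics, ROC points, McNemar paired comparisons and a
    model-selection grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
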