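Package: irimage
Title: Texture Statistics, Deep Classification and Uncertainty for
    Intestinal Ischemia-Reperfusion Surface Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying ischemia-reperfusion injury of the small
    intestine from RGB surface images. Provides a seeded synthetic
    tissue-image generator emulating the entropy, red-channel contrast and
    colour trends of intestinal ischemia and reperfusion over an 18-class
    hourly time course; Shannon entropy and gray-level co-occurrence (GLCM)
    texture statistics; from-scratch histogram-of-oriented-gradients (HOG)
    and local-binary-pattern (LBP) descriptors; a compact convolutional
    neural network trained with weighted cross-entropy and Adam; a
    decision-level fusion classifier that concatenates per-representation
    class probabilities and meta-classifies them with a random forest; a
    Bayesian convolutional network with Gaussian weight posteriors,
    reparameterised sampling and Monte-Carlo prediction intervals;
    macro-averaged evaluation metrics; and Shapley-value patch attribution
    with an exact enumeration oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    randomForest,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
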