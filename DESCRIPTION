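Package: pentumor
Title: Pancreatic-Tumor CT Classification with Metaheuristic-Tuned
    Segmentation and Autoencoder Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for binary tumor/non-tumor classification of grayscale
    CT-like images. The pipeline combines Gabor-filter texture preprocessing,
    multilevel Otsu thresholding with the threshold search performed by an
    emperor penguin optimizer, per-class statistical texture features, and a
    pair of per-class autoencoders whose weights and biases are tuned by a
    multileader population optimizer under a classification-error-rate
    fitness. A seeded phantom-image generator provides CT-like images with
    known ground truth so every stage is testable offline, and stratified
    train/test-split and k-fold evaluation protocols report sensitivity,
    specificity, accuracy and F-score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
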