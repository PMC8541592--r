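Package: countda
Title: Semi-Supervised Domain Adaptation for Holistic Image Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transferring a holistic counting model (image to a
    single real-valued count) from a labelled source image domain to a
    target domain that differs in appearance (covariate shift) and in count
    range (label gap). The pipeline pretrains a convolutional feature
    extractor and dense regressor on min-max normalised source labels,
    aligns target features to source features with an adversarial
    discriminator regularised by an output-variance term that prevents
    posterior collapse, monitors adaptation with a kernel maximum mean
    discrepancy statistic and the deviation of the discriminator mean
    output from one half, stops on a joint patience rule, and restores the
    target label range by fine-tuning the regressor on a handful of
    labelled target images. Includes a parameterised synthetic cell-scene
    renderer for constructing shifted source/target dataset pairs, the
    counting metrics (absolute and signed difference in count, mean squared
    error, percentage agreement), upper/lower-bound evaluation, a label
    budget sweep, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
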