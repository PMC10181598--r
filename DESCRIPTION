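Package: eogwave
Title: Wavelet-Based Classification of Electrooculography Eye Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying eye movements (down, up, blink, left,
    right) from two-channel electrooculography (EOG) recordings. Provides a
    synthetic EOG generator emulating a five-movement acquisition protocol,
    multilevel discrete wavelet decomposition with Shannon-entropy-guided
    mother-wavelet selection, windowed time/frequency feature extraction,
    from-scratch k-nearest-neighbour, polynomial-kernel support vector
    machine and Gini decision-tree classifiers, and evaluation via confusion
    matrices, ROC curves and the Jaccard index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    withr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
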