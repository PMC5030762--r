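Package: chunkrank
Title: Rank-Based Detection of Chunks in Response-Time Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Non-parametric segmentation of reaction-time (RT) series from
    sequence-learning tasks into chunks. Within each block of k repetitions
    of an N-item sequence, RTs are ranked per repetition, rank sums are
    differenced between consecutive items, and differences are tested
    against an exact critical value derived from the discrete convolution
    null distribution of rank-sum differences. Includes a chi-square index
    of chunking consistency, a planted-chunk RT simulator with a
    multiplicative-linear Gaussian noise model, and a Monte Carlo harness
    quantifying chunk-count and chunk-length recovery, error rates, and the
    effect of the number of repetitions per block.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
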