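Package: popbias
Title: Estimation Bias and Variance of Neural Population-Code Decoders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates stimulus decoding from small neural populations and
    quantifies the systematic bias and trial-to-trial variance of the
    population-vector, maximum-likelihood and Bayesian least-squares
    decoders. Supports rectified-cosine and von Mises tuning curves with
    Gaussian additive or Poisson spike-count noise, population scaling
    rules (density, amplitude, width) and linear sensor arrays. Provides
    Fisher information, the bias-corrected Cramer-Rao bound and decoder
    efficiency, and a fast analytical quadrature approximation to the
    Bayesian decoder's bias and variance under both noise models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
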