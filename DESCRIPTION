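Package: exwald
Title: Exwald Renewal-Process Models of Neural Interspike Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models the spontaneous discharge of vestibular semicircular-canal
    afferent neurons as stationary renewal processes.  Provides closed-form
    interspike-interval densities for eleven candidate families culminating in
    the Exwald distribution (the convolution of an Exponential and a Wald /
    Inverse Gaussian distribution, evaluated stably via the Faddeeva function),
    minimum Kullback-Leibler fitting with a bounded Nelder-Mead simplex,
    candidate ranking across a population of records, principal component
    analysis of fitted parameters in log space, and synthetic spike-train
    generation from the underlying physical mechanism (a Poisson trigger
    censored by an integrate-and-fire refractory process), so that every stage
    of the pipeline can be exercised and tested without access to raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
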