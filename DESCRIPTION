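Package: irthresh
Title: Item Response Thresholds Models for Mixed-Format Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and simulation for the general item response
    thresholds model P(Y > y) = F(alpha * (theta - delta(y))), a single
    latent-trait model covering binary, ordinal, count and continuous
    items, including mixed-format tests.  Provides marginal maximum
    likelihood fitting with Gauss-Hermite quadrature and analytic score
    functions, monotone B-spline difficulty functions with an optional
    shape penalty, EAP/MAP person scoring, item information functions,
    and likelihood-ratio tests for differential item functioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
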