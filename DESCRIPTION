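Package: ebbs
Title: Efficient Adaptive Administration of the Berg Balance Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shortening the 14-task Berg Balance Scale (BBS) fall-risk
    assessment by adaptive task sequencing with early stopping (Efficient-BBS).
    Builds a bank of random-forest fall-risk predictors over subsets of BBS
    tasks, offers four greedy next-task selector rules driven by ensemble vote
    confidence, runs simulated adaptive administrations that stop once a
    confidence threshold is reached, and evaluates the shortened battery with
    stratified cross-validation, occurrence matrices, confusion-matrix metrics,
    threshold adjustment for false-negative control, and intraclass correlation
    of total scores.  Includes an ordinal score simulator (binomial-logistic
    latent-ability model) so the full pipeline can be exercised without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    e1071,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
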