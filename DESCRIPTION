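Package: lookmix
Title: Within-Infant Uniform Mixture Models of Looking Style
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Fits a per-infant finite mixture of uniform distributions to
    trial-level difference scores from the paired-stimulus preferential
    looking paradigm. Each infant's looks are modelled as a mixture of one
    range-spanning "short look" uniform and two narrow boundary "long look"
    uniforms; an EM algorithm yields per-trial posterior short-look
    probabilities whose average is the infant's short-looking probability
    pi. Includes model diagnostics (empirical versus model CDF, variance
    ratios, serial-correlation checks), bootstrap uncertainty, weak and
    strong short-looker classification, and a downstream analysis suite
    linking looking style to stimulus preference across longitudinal
    occasions: transition probabilities, conditional means, delta-curves,
    bootstrap independence and precedence tests, trajectory extrapolation,
    and a binomial sampling-design calculator. A seeded synthetic-cohort
    generator emulates the longitudinal study design for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
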