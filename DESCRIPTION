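Package: ariannt
Title: Number Needed to Test with APOE Genotyping to Prevent ARIA Under
    Probabilistic Withholding Policies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian evaluation of APOE epsilon-4 homozygote screening as a
    safety policy for anti-amyloid antibody therapy. From genotype-stratified
    adverse-event contingency tables (amyloid-related imaging abnormalities,
    ARIA, by trial arm and epsilon-4/epsilon-4 status) the package samples
    stratum event rates from Jeffreys Beta-Binomial posteriors and computes
    the absolute risk reduction, number needed to test (NNT), fractional
    reduction in total ARIA events, and MRI-scaled NNT under a policy that
    withholds therapy from epsilon-4 homozygotes with probability p. Includes
    published phase-3 trial tables (lecanemab, donanemab) as built-in
    fixtures, Monte-Carlo sweeps over a grid of withholding probabilities
    with 95 percent credible intervals, a synthetic trial-table generator for
    parameter-recovery testing, and reporting utilities with a command-line
    entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
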