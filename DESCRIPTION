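Package: trialref
Title: Trial-Derived Adverse-Event Reference Sets via Symmetric Empirical-Bayes Denoising
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds denoised reference sets of drug-versus-drug adverse-event
    effects from public clinical-trial result records and evaluates
    non-experimental (observational) causal-inference methods against them.
    Trial records are filtered for randomized, participant-blinded,
    active-comparator designs; per-arm adverse-event counts are mapped to drug
    ingredient and outcome codes and pooled into 2x2 contingency tables. A
    symmetric nonparametric maximum-likelihood prior over log odds ratios is
    fitted by EM under the Fisher noncentral hypergeometric conditional
    likelihood, and each comparison's effect is denoised by its posterior mean.
    Reference subsets at increasing effect-size thresholds support scoring any
    method's per-comparison p-values and directions by concordant sign rate and
    recovery. Includes a seeded synthetic-data generator for trials,
    contingency tables from a known spike-and-slab prior, and method outputs
    with controllable power and bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
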