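Package: switchbf
Title: Task-Switching Control Indices and Sequential Bayes Factor Design Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cued task-switching experiments with four binary
    stimulus dimensions and 100%-switch sequences: a generative simulator of
    trial-level reaction-time and error data with known effect parameters,
    trial classification for the linear congruency effect, backward
    inhibition (n-2 task repetition) and competitor rule suppression,
    per-participant index computation with robust (MAD-based) and
    trial-count participant exclusion rules, default-prior (JZS)
    Bayes-factor t-tests and Bayesian correlations with Jeffreys evidence
    categories, exact noncentral-t power, and a Monte-Carlo simulator of
    Sequential Bayes Factor sampling designs with evidence boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
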