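Package: healmod
Title: Multi-Risk-Factor Markov Cohort Models for Economic Evaluation of
    Health-Promotion Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime Markov cohort model for the economic evaluation of
    school-based health-promotion programs acting jointly on weight status,
    physical activity, and fruit and vegetable consumption. The state space
    crosses the 24 joint risk-factor combinations with 33 chronic-disease
    statuses plus death (793 states). Program effects enter as odds
    multipliers on the baseline joint risk-factor distribution; risk-factor
    dynamics follow a joint multinomial-logit transition model; disease
    incidence and mortality are modulated by standardized rate ratios.
    Outputs are discounted quality-adjusted life years, years lived with
    chronic disease, health-care costs, incremental cost-effectiveness
    ratios and return on investment, with probabilistic sensitivity
    analysis, plus a synthetic-parameter generator for fully reproducible
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
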