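Package: spacerisk
Title: Lifetime Space Radiation Cancer Risk Projection Across Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime risk of exposure-induced cancer (REIC) and death (REID)
    from charged-particle space radiation, computed by folding Life Span Study
    excess-relative-risk models through population life tables with competing
    risks. Includes track-structure-motivated radiation quality factors with
    targeted-effects (TE) and non-targeted bystander-effects (NTE) variants,
    mixed-field folding over galactic-cosmic-ray-like ion spectra, a
    deterministic synthetic-population generator calibrated to published life
    expectancies and age-adjusted cancer incidence totals, mission exposure
    scenarios (annual GCR, Mars reference mission), and Monte-Carlo
    propagation of parameter uncertainty to confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
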