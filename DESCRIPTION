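Package: nlegacy
Title: Legacy Effects of Synthetic Nitrogen Fertiliser in Long-Term Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the legacy effect of sustained synthetic nitrogen
    fertiliser application from long-term field experiments (LTEs). Computes
    first-season fertiliser N recovery (by the withheld-N subplot method or by
    15N labelling), long-term apparent recovery against a never-fertilised
    control, and their difference (delta recovery, the legacy effect), then
    aggregates records across experiments with a weighted linear mixed model
    with crossed random intercepts for site and year, exhaustive AICc
    all-subsets model selection over agronomic and climatic co-variables, and
    method contrasts. Includes a synthetic LTE generator built on a multi-year
    fertiliser-N retention/remineralisation schedule so that every stage of the
    pipeline can be validated against known truth.
License: MIT + file LICENSE
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
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
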