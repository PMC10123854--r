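Package: mixriskscreen
Title: Cumulative Mixture-Risk Screening for Drinking-Water Contaminant Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-level cumulative risk assessment of inorganic and
    organic contaminant mixtures in drinking water. Implements detection
    and censoring quality assurance (method detection limit / limit of
    quantitation classification, blank-based censoring), precautionary
    health-benchmark resolution with substitution of zero maximum
    contaminant level goals, hazard-index screening (toxicity quotients
    summed under concentration addition), exposure-activity-ratio
    screening against high-throughput in vitro bioactivity tables,
    regulatory exceedance reporting, permutation statistics (one-way
    PERMANOVA on Euclidean distances and Spearman correlation with
    permuted probabilities), and a calibratable synthetic bottled-water
    study generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
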