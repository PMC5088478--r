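Package: amdcua
Title: Cost-Utility Analysis of Genetic Testing for Neovascular Macular Degeneration
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A value-based-medicine cost-utility model of genetic screening of
    Category 3 (large-drusen) age-related macular degeneration patients for
    progression to neovascular AMD. Implements the fellow-eye conversion
    recursion with last-observation-carried-forward extension, a discounted
    QALY value engine built on time-tradeoff vision utilities, a
    multi-perspective (societal and third-party insurer) cost ledger, national
    cost-utility and return-on-investment tables, break-even uptake solving
    against cost-effectiveness thresholds, a scenario engine for sensitivity
    analysis, and a patient-level Monte-Carlo microsimulation that serves as an
    independent oracle for the deterministic cohort model. All monetary values
    are 2012 US dollars discounted at 3 percent per year over a 12-year
    horizon.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
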