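Package: mangroveN
Title: Nitrogen Storage, Accumulation, and Food-Nitrogen Flows in
    Peri-Urban Mangrove Estuaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for nitrogen budgets of peri-urban mangrove estuaries
    from radiometrically dated sediment cores: per-slice and per-period
    nitrogen stocks and accumulation rates, percentile-bootstrap
    uncertainty with random pairing of accretion rate, bulk density and
    nitrogen content, estuary-wide upscaling by inverse-distance-weighted
    interpolation with skew-normal Monte-Carlo draws, a substance-flow
    model of human food nitrogen and its waste streams, porewater
    nutrient stoichiometry with non-detect handling, stable-isotope
    depth-profile regression with familywise-adjusted bounds, and a
    synthetic-core generator with ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
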