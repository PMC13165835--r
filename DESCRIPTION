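Package: vitidss
Title: Viticulture Agro-Climatic Decision Support Engines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical engines for vineyard decision support: ingestion,
    quality control, daily aggregation and nearest-station gap-filling of
    sub-daily weather observations; a seeded stochastic weather generator
    (sinusoid plus AR(1) temperature, Markov-chain/Gamma precipitation) for
    fully reproducible testing; annual viticultural bioclimatic indices
    (Winkler, Huglin, BEDD, cool-night, De Martonne, Branas, dryness) and
    multi-model ensemble climate normals; a recursive soil-water-balance
    Dryness Index with Thornthwaite evapotranspiration and irrigation
    alerts; Goidanich downy-mildew risk accumulation with the 3-10
    activation rule and management-coupled resets; growing-degree-day
    phenology forecasting for calibrated grape varieties with
    climatological percentile scenarios; and a minimal radiation-use
    efficiency yield simulator with FTSW water limitation. A command-line
    interface ties the engines together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
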