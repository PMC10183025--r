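Package: droughtsdi
Title: Daily Nonparametric Standardized Drought Indices (SPI, SPEI, SSMI)
Version: 0.1.0
Authors@R:
    person("Drought", "Tools", email = "drought@example.org", role = c("aut", "cre"))
Description: Computes daily standardized drought indices from site-level
    meteorological time series: the Standardized Precipitation Index (SPI),
    the Standardized Precipitation Evapotranspiration Index (SPEI) and the
    Standardized Soil Moisture Index (SSMI). Distributions are estimated
    nonparametrically with Gaussian kernel density estimation using
    least-squares cross-validated bandwidths, with an explicit mixture for
    the probability mass at zero precipitation, and mapped to standard
    normal scores by an equiprobability transformation. Includes
    Hargreaves-Samani potential evapotranspiration with latitude-derived
    extraterrestrial radiation, multi-scale rolling aggregation, drought
    classification schemes (McKee, Agnew, U.S. Drought Monitor), validation
    diagnostics, a seeded synthetic-weather generator, per-site CSV readers
    and writers, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
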