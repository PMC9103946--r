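Package: gwannSRMD
Title: Identifying the Spatial Range of Mining Disturbance on Vegetation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates the spatial range of mining disturbance (SRMD) on
    vegetation from multi-year fractional vegetation cover (FVC) and five
    driving factors (precipitation, temperature, topography, urban activity,
    mining activity). A geographically weighted artificial neural network
    (GWANN) relates the normalized drivers to FVC; a finite-difference
    attribution scheme converts the fitted surface into per-factor
    contributions; a "virtual" mining contribution computed over a pre-mining
    period calibrates an empirical noise distribution; and a one-sided
    significance test against the noise quantile yields the disturbance mask,
    summarised by disturbance distances, buffer containment and eight-sector
    directional ranges. Includes NDVI/FVC inversion by the pixel dichotomy
    model, cross-sensor NDVI harmonization, a seeded synthetic-scene generator
    with known ground truth, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    sp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
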