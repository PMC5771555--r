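Package: canopyflow
Title: Turbulence Processing and Fish-Count Statistics Around Model Seagrass Canopies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how canopy-forming nursery habitat modifies the
    near-bed water flow that juvenile fish experience. One arm processes
    acoustic Doppler velocimeter (ADV) burst records: phase-space threshold
    despiking, low-pass mean/fluctuation decomposition, streamline coordinate
    rotation with profile-level angle averaging, and inertial-subrange
    estimation of the turbulence energy dissipation rate via Taylor's
    frozen-turbulence hypothesis. The other arm analyses per-minute fish-count
    records: autocorrelation-based record thinning, median polynomial quantile
    regression against water velocity, and quasi-Poisson abundance and binomial
    water-column-proportion generalised linear models with Tukey HSD pairwise
    contrasts. A synthetic-data module generates velocity bursts with a known
    dissipation rate and count tables with known effects so that every stage
    has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    emmeans,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
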