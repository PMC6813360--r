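Package: lepiphen
Title: Phenology, Voltinism and Population Trends from Monitoring-Scheme Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking climate-driven phenology advances,
    voltinism and habitat specialisation to abundance and distribution trends
    in Lepidoptera, in the style of the British recording-scheme analyses.
    Fits per-population seasonal flight curves by penalized Poisson spline
    regression (REML smoothing), extracts first-generation peak days,
    inter-brood troughs and intergenerational abundance ratios, applies
    uniform data-selection criteria to count and atlas data, computes annual
    phenology, abundance, distribution and range-margin metrics together with
    spring growing degree days (GDD5), and estimates 20-year trends and
    interaction mixed models with likelihood-ratio tests. A synthetic-data
    generator emulates weekly transect and nightly light-trap monitoring plus
    hectad-scale atlas recording with known ground-truth parameters, so every
    stage is exercisable and testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    lme4,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
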