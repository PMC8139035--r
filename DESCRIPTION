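Package: mhscaleup
Title: Cost-Consequence Projection of Mental Health Service Scale-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the costs and health gains of scaling up a package of
    mental, neurological and substance-use (MNS) disorder interventions
    (anxiety, depression, bipolar disorder, epilepsy) over a multi-year
    horizon. Implements coverage scale-up trajectories under linear,
    front-loaded, S-shaped and exponential interpolation patterns,
    prevalence-based treated caseloads, three-component costing (drug and
    supply, delivery labor, programme overheads) with inflation and currency
    conversion, healthy-life-years-gained accounting, cost per healthy life
    year against GDP-per-capita thresholds, and a deterministic
    multi-scenario sensitivity analysis. Ships the published national
    projection tables for Iran's 2020-2030 socio-mental health service
    scale-up as reference fixtures, and a seeded synthetic input generator
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
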