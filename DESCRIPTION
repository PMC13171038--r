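Package: evtgap
Title: Neurointerventionalist Workforce Capacity and Endovascular
    Thrombectomy Access Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Country-level modelling of the link between neurointerventionalist
    workforce density and endovascular thrombectomy (EVT) uptake in ischaemic
    stroke. Provides a validated country-year panel data model, a synthetic
    panel generator with known generating parameters, Spearman rank
    correlations with Fisher z confidence intervals and an implied-sample-size
    solver, a cumulative expertise index and effective-supply trend analyses
    (first-difference and country fixed-effects regression), GDP-adjusted
    inversion of the fitted density-EVT model into per-country workforce gaps,
    and a log-linear counterfactual projection of stroke mortality under a
    uniform 15% EVT rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    lmtest,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
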