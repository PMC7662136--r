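Package: schoolyll
Title: Years of Life Lost Associated with US Primary School Closures
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model comparing years of life lost (YLL)
    attributable to COVID-19 under US primary-school closure (direct deaths
    plus education-mediated future mortality among children missing school)
    against a counterfactual in which schools remained open and direct
    mortality scaled by a school-opening mortality ratio.  Provides seeded
    Monte Carlo sampling (PERT and truncated-normal parameters), period
    life-table construction from printed life-expectancy anchors,
    proportional hazard adjustment for the education-mortality gradient,
    discounting of future life-years, a synthetic generator for the child
    population and state school-closure durations, and an end-to-end
    scenario comparison with credible intervals and exceedance
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
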