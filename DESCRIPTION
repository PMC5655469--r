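Package: oaburden
Title: Lifetime QALY Burden of Knee Osteoarthritis by Monte Carlo Microsimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates lifetime quality-adjusted life year (QALY) losses
    attributable to knee osteoarthritis in an adult population, stratified by
    5-year age band, sex, and ethnicity. Individuals are simulated through
    annual cycles of WOMAC pain progression and life-table mortality; yearly
    EQ-5D utilities by age and pain severity are summed into quality-adjusted
    life expectancy (QALE), and burden is derived by differencing the QALE of
    matched cohorts with and without knee osteoarthritis under counterfactual
    age weighting. Includes synthetic generators for life tables, census-style
    population counts, and prevalence surfaces; a Torrance-style power
    transform between VAS- and trade-off-consistent value sets; and
    probabilistic sensitivity analysis over the non-osteoarthritis pain
    distribution and prevalence adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
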