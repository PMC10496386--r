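Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for Second-Line
    Therapy in Advanced Intrahepatic Cholangiocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) partitioned
    survival cost-effectiveness engine built around the published evaluation of
    pemigatinib versus mFOLFOX and 5-FU chemotherapy as second-line treatment
    for advanced intrahepatic cholangiocarcinoma with FGFR2 fusions, from the
    payer perspective of Taiwan's National Health Insurance Administration.
    Provides parametric survival laws (Weibull, log-normal, generalized gamma)
    with discounted restricted mean survival, maximum-likelihood refitting on
    right-censored pseudo individual patient data, Kaplan-Meier estimation and
    hybrid KM-plus-parametric curve construction, cohort simulation with
    half-cycle correction, incremental cost-effectiveness ratios and net
    monetary benefit, deterministic (tornado) and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves and expected value of
    perfect information, and price-reduction and structural scenario analyses.
    A configuration fixture ships the full published parameter table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    flexsurv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
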