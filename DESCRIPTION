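Package: pahcea
Title: Cost-Utility and Budget-Impact Modelling of Pulmonary Selective
    Drug Therapy for Pulmonary Arterial Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state Markov cohort model (WHO functional classes
    I-IV plus death, three-month cycles) for the economic evaluation of
    pulmonary selective drug therapy in pulmonary arterial hypertension.
    Implements treatment effects as relative risks on baseline
    functional-class switching probabilities, discounted life-year, QALY
    and cost accumulation, incremental cost-effectiveness and net
    monetary benefit analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, one-way and threshold drug
    price analyses, a five-year open-cohort budget impact projection,
    and a patient-level synthetic cohort generator with method-of-moments
    parameter re-estimation. All model inputs live in a single YAML
    configuration; a transcription of the published parameter table is
    bundled as the default.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
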