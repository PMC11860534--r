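Package: hrsc
Title: Heart-Rate Slow Component Modelling for Constant-Load Exercise
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation, cleaning and analysis of breath-by-breath
    cardiopulmonary exercise data centred on the heart-rate slow component
    (scHR), the progressive rise of heart rate during constant-load exercise
    that is partially dissociated from oxygen uptake. Provides a synthetic
    generator for age- and sex-stratified subjects and their ramp and
    constant-work-rate responses; breath-by-breath cleaning (prediction-band
    outlier rejection, 1-s interpolation, 5-s binning); ramp-derived maximal
    parameters, mean response time and intensity-domain anchoring at the gas
    exchange threshold and respiratory compensation point; per-trial scHR and
    oxygen-pulse metrics; forward multiple regression with correlation and
    variance-inflation screening to fit an intensity-age-sex prediction
    equation; and Bland-Altman agreement analysis of dynamically projected
    heart-rate targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
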