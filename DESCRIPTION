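Package: heatwear
Title: Wearable Health Outcomes Under Heat and Rainfall Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking consumer-wearable health outcomes
    (daily step counts, nightly sleep duration, nighttime heart rate) to
    weather-station-derived heat and rainfall exposure in a rural
    single-timezone panel study. Implements weather-station processing
    (NWS heat index, wet-bulb globe temperature estimation, climate extreme
    indices, day/night exposure windows, nearest-station assignment on the
    WGS 84 ellipsoid), wearable quality control (wear-time filtering, sleep
    record merging, heart-rate ceilings, completeness criteria), exposure
    linkage, and a linear mixed-effects modelling workflow with stepwise
    covariate selection, quadratic heat terms, subgroup interactions,
    binary extreme-weather contrasts, AIC-based heat-metric comparison and
    leave-one-subject-out cross-validation, together with a fully
    parameterised synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
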