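Package: boarheat
Title: Wild Boar Activity Under Summer Heat from Biologging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing the activity of wild boar
    (Sus scrofa) under summer weather from multisensor biologging collars.
    Computes the vectorial sum of dynamic body acceleration (VeDBA) from raw
    triaxial accelerometer streams, aggregates activity over sunrise-anchored
    biological days, detects heatwaves from daily temperature, derives daily
    GPS movement metrics (distance travelled, maximum net squared displacement,
    mean speed), and fits generalized additive mixed models of diel and
    seasonal activity plus a linear mixed model of activity within heatwaves.
    Ships a synthetic-data generator with the statistical structure the
    analysis assumes, so the full pipeline is testable without field telemetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
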