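Package: calvetrend
Title: Calving-Time Alerts from Heart-Rate Trend Turning Points
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for predicting cow calving time from Holter
    R-R interval recordings. Beat-level R-R series are cleaned with a running
    30 percent outlier rule, averaged onto a 30-minute grid, gap-imputed, and
    decomposed by STL (seasonal-trend decomposition using LOESS) into trend,
    daily cycle and remainder. Financial technical indicators (simple and
    exponential moving averages, moving average deviation rate, MACD and RSI)
    are computed on the trend and their peaks are taken as the trend turning
    point, an early calving signal; remaining hours to calving are summarised
    and indicators compared with a randomized-block / mixed-model analysis.
    A seeded synthetic R-R generator with known ground truth supports
    end-to-end testing and turning-point recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
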