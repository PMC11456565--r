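Package: turnload
Title: Cognitive-Load Analysis of Simulated-Flight Turning Behaviour from
    Heart-Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pilot cognitive load during flight-simulator
    turning manoeuvres from wearable heart-rate data. Simulates flight
    telemetry following a training flight plan together with beat-to-beat
    RR-interval series whose autonomic structure depends on the turn-load
    class; cleans RR artifacts by local-median detection and linear
    interpolation; segments and classifies turns (climbing, leveling,
    descending) from heading and altitude; extracts 30 standard
    heart-rate-variability features on 30-second sliding windows; screens
    features by normality-routed ANOVA or Kruskal-Wallis tests; and
    classifies turn-load classes with k-nearest-neighbour, random-forest,
    LSTM, and LSTM-with-self-attention models, evaluated by macro
    precision/recall/F1 and one-vs-rest ROC/AUC.
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
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    class,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
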