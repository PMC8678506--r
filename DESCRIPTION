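Package: sicdic
Title: Early Dynamic Sequential Prediction of Sepsis-Induced Coagulopathy and Overt DIC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for early, sliding-window prediction of sepsis-induced
    coagulopathy (SIC) and sepsis-associated overt disseminated intravascular
    coagulation (DIC) from irregular laboratory time series. Provides a
    synthetic sepsis cohort generator with informative missingness, SIC and
    ISTH overt-DIC scoring with two-step sequential diagnosis and windowed
    label timelines, mask/time-interval encoding of irregular streams,
    continuous-time sequence models (RNN-Decay, ODE-RNN) alongside
    discretized RNN/LSTM and tabular baselines, horizon-wise evaluation with
    patient-level bootstrap confidence intervals, and occlusion/SHAP-based
    model interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    data.table,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
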