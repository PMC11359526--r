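Package: stressdge
Title: Explainable Short-Term Stress Detection from Wearable EDA and Skin
    Temperature with Deep Generative Ensembles
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting short-term (16 s) stress responses in
    wearable electrodermal activity (EDA) and skin-temperature recordings.
    Provides a synthetic-cohort simulator of laboratory stress protocols
    (phasic skin-conductance responses with latency/rise/recovery structure,
    non-responders, spurious peaks), a signal-processing chain (low-pass
    denoising, first-order 0.05 Hz high-pass phasic extraction, 4 to 1 Hz
    downsampling, standardization, sliding 16 s windows), an LSTM sequence
    classifier with orthogonal/xavier initialization and forget-gate bias 1,
    noise/amplitude augmentation plus a conditional generative model and the
    Deep Generative Ensemble (DGE) training scheme, Integrated Gradients
    feature attribution with cohort averaging, and event-based evaluation of
    predicted moments of stress against reference stressors using asymmetric
    (-2 s/+6 s) matching windows and an 8 s merging rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
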