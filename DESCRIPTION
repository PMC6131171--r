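Package: psicat
Title: Primed Subjective-Contour Attention Task: Stimuli, Protocol, Simulation and EEG Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Primed Subjective Illusory Contour Attention Task
    (PSICAT), a two-alternative forced-choice continuous performance test built
    on Kanizsa subjective-contour stimuli. Generates constrained irregular
    Kanizsa targets with Pac-Man inducers and congruent or incongruent line
    primers, builds randomized trial schedules with realistic timing, simulates
    complete behavioural and multichannel EEG sessions with calibrated response
    and component models, and analyses the results: participant-wise rank tests
    with z-based effect sizes, a windowed-amplitude ERP pipeline with
    dual-baseline correction and region-of-interest averaging, early-versus-late
    spectral comparisons (Welch power spectra, event-related spectral
    perturbation, inter-trial coherence) with label-shuffle permutation testing,
    and pooled effect-size reporting comparing task-irrelevant congruency
    effects against task-relevant gestalt effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    signal,
    png,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
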