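Package: motormapr
Title: Somatotopic and Shared-Representation Mapping from Intracranial Motor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for stereo-EEG motor mapping experiments:
    bipolar rereferencing of depth-electrode recordings, EMG-defined movement
    epoching, Welch trial spectra with a signed r-squared movement-versus-rest
    statistic, somatotopic delineation by complex vector sum, geometric-mean
    overlap scoring of shared movement representation, Hilbert-envelope
    broadband timecourses with brain-EMG latency estimation, penalty-based
    k-means parcellation of channels, and linear-discriminant movement
    decoding. Includes a synthetic sEEG+EMG session generator with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
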