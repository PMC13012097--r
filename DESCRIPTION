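Package: isocouple
Title: Directed Coupling of Infraslow Hemodynamic, Electrical, and Water Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for directed coupling among infraslow (<0.1 Hz)
    hemodynamic (BOLD-like), electrophysiological (EEG-like), and tissue water
    concentration (NIRS-like) time series across arousal states. Provides
    zero-phase FIR band-limiting with mirror padding, Hilbert-phase extraction,
    discrete phase transfer entropy with a net-direction statistic (delta TE),
    Morlet wavelet time-frequency power on a logarithmic grid with infraslow
    band integration, and a group-inference layer combining Wilcoxon rank-sum
    tests with false discovery rate control and randomization tests with
    threshold-free cluster enhancement (TFCE). A synthetic multimodal generator
    with known directed phase coupling and state-dependent power supports
    ground-truth recovery testing of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
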