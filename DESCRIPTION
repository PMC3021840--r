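Package: meegflow
Title: Trial-Based MEG/EEG Analysis: Spectra, Connectivity, Source
    Reconstruction and Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolbox for multichannel electrophysiology
    (MEG/EEG): a trial-based data model with nested provenance,
    BrainVision Analyzer file input/output, time-domain preprocessing,
    z-threshold artifact detection with PCA-based component removal,
    multitaper (DPSS) and wavelet spectral estimation, frequency-domain
    connectivity (coherence, PLV, PSI, PDC, DTF, spectral Granger
    causality from fitted MVAR models), analytic sphere-model forward
    solutions (MEG single sphere, EEG concentric spheres), dipole
    fitting, minimum-norm estimates and LCMV/DICS beamformers,
    nonparametric cluster-based permutation statistics, and seeded
    synthetic-data generators that exercise every analysis path through
    the package's own forward models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
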