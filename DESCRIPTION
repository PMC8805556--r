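Package: fluorephys
Title: Bimodal Fluorescence and Extracellular Electrophysiology Probe
    Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Photon-transport Monte Carlo for implanted-photodiode
    fluorescence neural probes (illumination fluence, detection-probability
    maps, fluorescence detection volume, stimulation-light crosstalk), a
    seeded generator of bimodal recordings (GCaMP-like photodiode current at
    60 Hz plus 30 kHz multichannel extracellular voltage with an optical
    stimulation schedule), and the signal-analysis chain that classifies
    sorted extracellular units as calcium-indicator-positive or -negative
    from the correlation between their firing and the photodiode signal:
    Butterworth baseline correction and dF/F, transient detection and
    kinetics, greedy spike-count inference, band-pass filtering and spike
    sorting, unit trilateration from per-channel amplitudes, rise/rest and
    stimulation ON/OFF firing-rate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
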