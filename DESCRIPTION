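Package: snnHFO
Title: Spiking Neural Network Detection of High-Frequency Oscillations in EEG
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting high-frequency oscillations
    (HFO; ripples 80-250 Hz and fast ripples 250-500 Hz) in intracranial EEG,
    intraoperative ECoG and scalp EEG with spiking neural networks. Signals are
    band-pass filtered, converted to UP/DN spike trains by a baseline-adaptive
    asynchronous delta modulator, and fed to leaky integrate-and-fire networks
    with heterogeneous exponential synapses: a core detection layer, a
    dis-inhibitory in-band artifact-rejection circuit, and a parallel
    high-frequency (>500 Hz) artifact-detection network. Second-layer rasters
    are converted to HFO events by 15 ms window marking, and per-channel HFO
    rates drive clinical decision rules (HFO-area resection overlap, residual
    HFO rate, affected-hemisphere median rate) with exact binomial confidence
    intervals, rate/seizure-frequency regression and SNR measurement. Includes
    a deterministic synthetic EEG generator with annotated ground truth for
    validating every stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'snnHFO-package.R'
    'RcppExports.R'
    'bandpass.R'
    'spike-codec.R'
    'synthetic-data.R'
    'edf.R'
    'eeg-io.R'
    'snn-engine.R'
    'event-detection.R'
    'clinical-stats.R'
    'pipeline.R'
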