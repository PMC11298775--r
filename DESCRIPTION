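Package: gemsort
Title: Streaming Graph-Network Spike Sorting for Multichannel Extracellular Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements GEMsort, a streaming spike-sorting pipeline for densely
    spaced multichannel extracellular probes. Raw voltages are high-pass
    filtered and cleaned with local common average referencing, spikes are
    detected with a per-channel robust 5-sigma threshold, duplicate copies of
    the same action potential recorded on adjacent channels are collapsed to
    the highest-amplitude representative, and representative waveforms are
    projected onto principal components learned from an initial training batch
    and augmented with the recording-channel position. Clustering is performed
    online by a growing-neural-gas graph whose connected components track the
    neuron clusters, so each spike is classified in a single pass without
    retaining past waveforms. The package also ships a synthetic 16-channel
    recording generator with exact ground truth (Poisson firing, four wavelet
    template families, 1/r distance attenuation, Gaussian noise) and
    evaluation tools: ground-truth accuracy scoring with optimal one-to-one
    cluster assignment, two-sorter agreement matrices, and autocorrelograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
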