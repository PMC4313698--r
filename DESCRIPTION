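Package: ppsnet
Title: Audio-Tactile Peripersonal Space Network Simulation and Boundary
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rate-based neural network model of audio-tactile peripersonal
    space (PPS) around the hand: two unisensory neuron grids with
    hand-centered receptive fields and Mexican-hat lateral connectivity
    project through Hebbian-plastic feedforward synapses onto a single
    multisensory unit, which returns excitatory feedback. The package
    simulates unimodal receptive-field mapping and audio-tactile
    reaction-time protocols before and after synchronous or asynchronous
    audio-tactile training, fits the sigmoid boundary model used to locate
    the peripersonal-space boundary (central point with 95 percent
    confidence interval), and provides the companion behavioral
    reaction-time pipeline (delay-to-distance recoding,
    two-standard-deviation trimming, per-session boundary fits) together
    with bundled reference means and a synthetic trial generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
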