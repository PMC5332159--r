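Package: spasmpipe
Title: Quantitative Analysis of Spinal Spasm Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for the quantitative analysis of
    spasm-related spinal recordings after sacral spinal cord injury: motor-unit
    spike detection, template matching and firing-phenotype classification
    (long-lasting, bimodal, high, low) with a Hartigan dip test of bimodality;
    motor-neuron plateau-property assessment from triangular current ramps
    (recruitment/de-recruitment currents, delta-I, f-I hysteresis); synaptic
    event detection and excitation/inhibition balance; reflex quantification
    and four-epoch spasm segmentation of root recordings; delta-F/F calcium
    trace analysis with peri-event piecewise time normalization onto the
    canonical [-1, 3] epoch axis and Gaussian/mixture fits of population peak
    times. A synthetic-session generator emulates every recorded modality with
    known ground truth so each analysis stage has parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    zoo
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
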