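Package: engdecode
Title: Decoding Phantom Limb Movements from Intraneural Electroneurography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Offline analysis stack for multichannel intraneural
    electroneurography (ENG) recorded with transversal intrafascicular
    multichannel electrodes during attempted (phantom) lower-limb movements.
    Provides powerline-notch and Butterworth band filtering, multiunit spike
    detection at a standard-deviation threshold, firing-rate and z-score
    modulation maps with joint/direction selectivity matrices, leaky
    integrate-and-fire event encoding of the continuous signal, a shallow
    spiking neural network classifier trained with a surrogate gradient,
    conventional SVM and MLP baselines on RMS/power/spike-rate features,
    Herdin correlation-matrix distances between neural and muscular
    activation maps, and a seeded protocol-faithful synthetic recording
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    nnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
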