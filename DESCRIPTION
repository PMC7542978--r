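Package: gaitglove
Title: Finger-Gaiting Analysis of Data-Glove Manipulation Time Series
Version: 0.1.0
Authors@R:
    person("Martin", "Hartkamp", email = "m.hartkamp@posteo.net",
           role = c("aut", "cre"))
Description: Tools for decomposing repeated in-hand object manipulations
    recorded with a multi-sensor data glove into grasp-configuration
    components and for testing the finger-gaiting hypothesis. Provides
    per-run principal component analysis with two-stage sign alignment,
    a k-means taxonomy of sensor expression patterns under correlation
    distance, frequency and bounded-lag delay statistics of component
    time courses, signed weighted correlation networks over the key
    finger-joint sensors (global efficiency, small-world metrics,
    Louvain modules), and 3D fingertip trajectory segmentation with
    resampled mean trajectories and confidence ellipsoids. A synthetic
    generator with known ground truth (loadings, frequencies, phase
    delays, noise) supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
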