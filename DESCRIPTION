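Package: strokecoach
Title: LSTM Stroke Classification and Latent-Trajectory Coaching for IMU Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for skill assessment from body-worn inertial measurement
    unit (IMU) recordings of table-tennis strokes. Provides a synthetic
    stroke generator emulating a two-subject (coach/beginner), five-skill
    factorial design; stacked unidirectional and bidirectional LSTM
    sequence classifiers trained by backpropagation through time with Adam;
    magnitude pruning with mask-frozen retraining; a deep Markov model
    (nonlinear Gaussian state-space model) fitted by structured variational
    inference over the classifier's hidden-state embeddings; and coaching
    utilities that compare a player's low-dimensional latent stroke
    trajectories against reference trajectories. Includes a Kalman-filter
    log-likelihood oracle for validating the evidence lower bound on
    linear-Gaussian instances, delimited-text data interchange, and an
    end-to-end pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
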