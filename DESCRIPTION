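Package: pembench
Title: Prediction-Error Benchmarking of Linear and Nonlinear Models for
    Multivariate Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-validated one-step-ahead prediction-error system
    identification for channels-by-time neural recordings. Implements a common
    fit/predict contract for linear first-difference (vector) autoregressive
    models with optional LASSO sparsity, stochastic subspace state-space
    models, locally linear (model-on-demand) predictors, conditional-mean
    (MMSE) predictors estimated by Gaussian-windowed weighted histograms, a
    small multilayer-perceptron NARX model, and the zero-order-hold baseline.
    Scoring includes per-channel prediction R-squared, a multivariate
    portmanteau residual-whiteness statistic with a randomization threshold,
    cross-validation plans for fMRI-like and iEEG-like recordings, and
    one-sided signed-rank model comparison with false-discovery-rate control.
    A synthetic-data suite generates ground-truth stable vector
    autoregressions, static sigmoidal (tanh) relations, distance-correlated
    Gaussian fields on a unit sphere, power-law (1/f^p) signals, noise
    injection at a prescribed signal-to-noise ratio, and Izhikevich spiking
    neurons, and a set of experiment drivers quantifies how spatial averaging,
    spatial correlation, temporal low-pass filtering, observation noise, and
    sample-limited dimensionality linearize macroscopic dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
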