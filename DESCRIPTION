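Package: focusrl
Title: Reinforcement-Learning Autofocus on Synthetic Liquid-Lens Focal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying image-based autofocus of voltage-driven
    (liquid-lens) microscopes with deep reinforcement learning. Provides a
    synthetic through-focus stack simulator (textured samples, voltage-indexed
    Gaussian defocus, augmentation, on-disk PNG+JSON stacks), standard focus
    measures, discrete voltage action-set constructions, a hybrid shaped reward
    (sharpness, time-step, stop and extreme-image components with ablation
    gates), an episodic autofocus environment with random sampling over focal
    stack lists, a deep Q-learning agent with experience replay and a target
    network, golden-section and Fibonacci search baselines, and scripted
    experiment runners with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
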