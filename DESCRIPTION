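Package: flexgait
Title: Neuromuscular Simulation of Human Walking with Voluntary Swing-Leg Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Layered neuromechanical model of human locomotion. A seven-segment,
    14-degree-of-freedom biped actuated by 22 Hill-type muscle-tendon units is
    controlled by a spinal layer (generic stretch reflexes for the swing leg,
    five functional reflex modules for the stance leg) and a supraspinal layer
    that plans minimum-jerk swing-leg movements on the task level, updates them
    in real time for balance and obstacle avoidance, and transforms them into
    descending motor commands through internal models (inverse dynamics,
    non-negative muscle-force distribution, inverse muscle model and reflex
    inversion). Includes compliant ground contact, sensor delay lines, CMA-ES
    tuning of the 55 free controller parameters, and the simulation experiments
    (center-out reaching, sinusoid tracking, randomized reaches, steady walking,
    push perturbations, obstacle avoidance, speed and direction modulation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
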