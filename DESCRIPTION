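Package: cardiolpm
Title: Closed-Loop Cardiovascular Lumped-Parameter Modelling with LVAD
    Support and Non-Invasive Parameter Estimation
Version: 0.1.0
Authors@R:
    person("LPM", "Maintainers", email = "maintainers@cardiolpm.org",
           role = c("aut", "cre"))
Description: Simulates a twelve-compartment closed-loop lumped-parameter
    model (LPM) of the human circulation with an optional continuous-flow
    left ventricular assist device (LVAD), including time-varying chamber
    elastances, smoothed diode valves, a quadratic pump pressure-flow law
    and a suction resistor.  Provides clinical hemodynamic indicators
    (cardiac output, arterial and pulmonary pressures, pressure-volume
    loops, ramp tests), traditional and generalized sensitivity analysis
    (TSF/GSF/Fisher information) for parameter-subset selection,
    Latin-hypercube synthetic dataset generation, a hierarchical
    convolutional/MLP estimator that maps echocardiography-style waveforms
    and blood pressure to patient-specific model parameters through an
    exact end-systolic elastance bridge, and the evaluation metrics used
    to benchmark the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
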