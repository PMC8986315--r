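Package: channelreg
Title: Homeostatic Coregulation of Ion Channel Densities in a
    Conductance-Based Model Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single-compartment conductance-based neuron whose
    spikes are generated by Morris-Lecar fast/slow conductances, with
    additional adjustable sodium, potassium, M-type, AHP-type and leak
    conductances. Measures neuronal properties (firing rate under
    Ornstein-Uhlenbeck stimulation, rheobase, minimum sustainable rate,
    interspike-interval variability, input resistance, Na+/K+-pump energy
    consumption and per-spike energy efficiency), maps single- and
    multi-output solution sets over conductance-density grids, extracts
    iso-property manifolds and their intersections, and implements an
    integral-feedback homeostat that coadjusts channel densities via signed
    per-channel regulation rates, including lower-bound targets and
    conductance noise. Includes turnkey scenario drivers for knockout
    compensation, solution-set intersection scans, correlation emergence
    and regulation-failure experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
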