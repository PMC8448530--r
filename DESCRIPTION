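Package: neuroimpact
Title: Explicit-Dynamics Simulation of Concussive Mouse-Brain Impact and a
    Flow-Cytometry Neurodegeneration Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plane-strain explicit-dynamics finite-element simulation of a
    region-partitioned, linearly viscoelastic sagittal mouse-brain section
    (Prony-series shear relaxation per brain region, elastic skull, rigid
    impactor with frictionless penalty contact), with synthetic parametric
    geometry generation, monitor-point stress/strain time histories, von
    Mises and principal-strain postprocessing, and an energy ledger.  Also
    implements a large-particle flow-cytometry neurodegeneration readout for
    sorted C. elegans populations: per-repeat GFP retention indices,
    empty-vector normalization, and quadrature error propagation, together
    with a synthetic sort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
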