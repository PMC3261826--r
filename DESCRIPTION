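Package: neutronplan
Title: Voxel Monte Carlo Dose Engine for Fast-Neutron Therapy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained Monte Carlo simulator for first-steps fast-neutron
    treatment planning at a reactor-based therapy beamline. Samples binned
    neutron and photon source spectra by inverse-CDF, transports particles
    through solid-box and voxelised water phantoms and a voxelised
    anthropomorphic head phantom with a simplified neutron/photon interaction
    model (free-gas thermal scattering, 1/v capture, Klein-Nishina Compton,
    kerma approximation for charged particles), scores absorbed dose per
    particle type with history-by-history statistical errors, and derives the
    planning outputs: depth-dose curves, lateral profiles, dose-volume
    histograms, RBE-weighted dose grids, and isodose contours.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
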