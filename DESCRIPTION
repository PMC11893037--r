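Package: prefulr
Type: Package
Title: Free-Breathing 3D Lung MRI Ventilation Mapping with
    Motion-Compensated Low-Rank Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for free-breathing
    phase-resolved functional lung (PREFUL) MRI. Generates 3-hub
    Fermat-spiral (FLORET) center-out k-space trajectories, a dynamic
    digital breathing-thorax phantom with configurable ventilation
    defects, respiratory binning of continuously acquired excitations
    from a bellows trace (Hilbert-phase, equal-count bins with bounded
    view sharing), motion-compensated low-rank (MoCoLoR) reconstruction
    of respiratory-resolved image series via a gridding NUFFT, and 3D
    PREFUL postprocessing producing regional ventilation (RVent),
    flow-volume-loop cross-correlation (FVL-CM) and ventilation
    time-to-peak (VTTP) maps with ventilation defect percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'binning.R'
    'io.R'
    'metrics.R'
    'nufft.R'
    'phantom.R'
    'pipeline.R'
    'preful.R'
    'prefulr-package.R'
    'recon.R'
    'registration.R'
    'trajectory.R'
    'utils.R'
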