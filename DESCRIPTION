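Package: shiftgrid
Title: Grid-Based Additive Prediction of Protein Backbone Chemical Shifts
Version: 0.1.0
Authors@R:
    person("shiftgrid", "developers", email = "shiftgrid@example.org",
           role = c("aut", "cre"))
Description: Predicts isotropic chemical shielding values for protein
    backbone atoms and C-beta from three-dimensional structure using an
    additive decomposition: a tripeptide backbone term indexed by
    phi/psi/chi torsions, neighbour side-chain corrections, primary and
    secondary hydrogen-bond corrections parameterised by
    (distance, angle, dihedral) geometry, a point-dipole ring-current
    term for protons, and a water correction for solvent-exposed amide
    protons.  Shielding hypersurfaces are stored in a portable grid
    bundle and interpolated with periodic cubic or nearest-neighbour
    schemes.  Predicted shieldings are converted to chemical shifts by
    linear regression against experiment, with random-coil subtraction
    and generalized extreme studentized deviate outlier diagnostics.
    A synthetic-surface generator makes the full pipeline testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
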