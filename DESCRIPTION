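Package: thermoshift
Title: Design and Evaluation of Thermo-Stabilizing Extramembrane Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools for rational thermostabilization of membrane proteins in
    their extramembrane regions. Implements candidate selection for single
    mutations from predicted folding free-energy changes; structural-ensemble
    statistics for molecular-dynamics snapshot series (C-alpha superposition
    RMSD against a crystal reference, medoid representative selection and the
    derived random-coil fluctuation statistic, per-residue deviations,
    ion-pair distance occupancy, radius of gyration traces); analytics for
    experimental stability measurements (residual pigment, single-exponential
    decoloration kinetics, differential scanning calorimetry processing and
    melting-temperature extraction); and a branching statistical comparison
    protocol (Kolmogorov-Smirnov normality screen, F-test on variances, then
    Student's or Welch's two-tailed t-test). Seeded synthetic-data generators
    emulate every input so the full pipeline is testable without simulations
    or instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
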