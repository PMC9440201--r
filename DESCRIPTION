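Package: deerfit
Title: Global Analysis of DEER Spectroscopy Data for Proton-Coupled
    Conformational Equilibria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and global multi-Gaussian analysis of
    four-pulse DEER (double electron-electron resonance) dipolar evolution
    traces, with statistical model selection and delta-method or bootstrap
    confidence bands on the distance distribution P(r). Downstream tools
    estimate the pK and Hill coefficient of pH-coupled conformational
    transitions from fitted state populations, predict inter-spin-label
    distance distributions from PDB structures with an accessible-volume
    label model, and compute orientation-based collective variables,
    salt-bridge time series and harmonic distance-restraint energies for
    transporter alternating-access analysis. A synthetic-data module
    generates pH-coupled two-state DEER datasets, titration tables, toy
    helix bundles and salt-bridge trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
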