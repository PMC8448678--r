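Package: assemblyED
Title: Essential Dynamics and Trajectory Analysis for Tubulin Assemblies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of molecular dynamics trajectories of tubulin
    assemblies (protofilament sheets and microtubule fragments): Kabsch
    least-squares superposition and RMSD series, essential dynamics by
    principal component analysis of concatenated heterodimer
    trajectories, scree/Cattell diagnostics, eigenvector overlap and
    RMSIP convergence curves, protofilament bending-angle statistics,
    van Hove self-correlation and self-intermediate scattering
    functions, and axis-resolved mass density profiles.  Includes a
    synthetic assembly-trajectory generator with planted orthonormal
    modes so every analysis stage is testable by parameter recovery
    without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
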