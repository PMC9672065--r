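Package: mshk
Title: Multistate Machine-Learned Hohenberg-Kohn Maps for Excited-State
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel ridge regression maps from Gaussian-smeared molecular
    external potentials to ground- and excited-state electron densities
    expanded in a Fourier basis, together with a single multistate
    density-to-energy functional (ML-MSHK) and a direct state-specific
    potential-to-energy map (ML-MSKS).  Includes the training-set
    construction pipeline (alignment, mirror-plane canonicalization,
    K-means selection under the L2 potential metric, reflection doubling),
    an NVE/Langevin molecular-dynamics engine with numerical forces and a
    planarity restraint, non-equilibrium proton-transfer observables with
    bootstrap confidence bands, and an analytic multistate surrogate
    oracle for a planar malonaldehyde-like molecule so the whole framework
    is trainable and verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
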