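Package: liverEIT
Title: Electrical Impedance Tomography of Hepatic Steatosis on 2-D Abdomen Phantoms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction pipeline for abdominal electrical
    impedance tomography (EIT) aimed at non-invasive quantification of liver
    fat. Builds parametric 2-D abdomen phantoms with labelled organ regions,
    solves the conductivity (Laplace) forward problem with a linear
    finite-element method and a complete or point electrode model, generates
    skip-pattern stimulation frames, and reconstructs absolute conductivity
    maps by iterated Gauss-Newton minimization with Tikhonov regularization
    and an anatomically weighted Laplacian prior. Includes a synthetic
    overweight-cohort generator with a monotone liver-conductivity versus
    fat-fraction relationship, printed study tables as packaged fixtures, and
    the cohort correlation analysis (Pearson tests, slope confidence
    intervals, Bonferroni correction, exclusion-rule variants).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Matrix,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry-utils.R'
    'phantom.R'
    'mesh.R'
    'mesh-io.R'
    'pattern.R'
    'forward.R'
    'noise.R'
    'jacobian.R'
    'regularization.R'
    'inverse.R'
    'cohort.R'
    'cohort-pipeline.R'
    'roi.R'
    'stats.R'
    'fixtures.R'
    'pipeline.R'
    'plots.R'
    'liverEIT-package.R'
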