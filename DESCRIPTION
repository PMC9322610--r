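Package: eitgwo
Title: Electrical Impedance Tomography with Grey-Wolf-Optimised RBF Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale electrical impedance tomography (EIT) toolkit for a
    16-electrode circular sensor. Provides a 2D finite-element forward solver
    with the adjacent drive / adjacent measurement protocol, random circular
    phantom generation with forward-solved boundary-voltage datasets, and
    three image reconstructors: Landweber iteration on the adjoint-field
    sensitivity matrix, a radial basis function neural network (K-means
    centres, maximum-distance width rule, least-squares output weights), and
    a grey wolf optimiser acting on the network's output weights. Includes
    RMSE and image-correlation quality metrics, Gaussian noise injection at
    prescribed SNR, and an experiment driver that reproduces the full
    simulation study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
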