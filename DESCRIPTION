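Package: omegaCP
Title: Smooth Surrogate Models of Conical Intersection Seams via
    Characteristic Polynomial Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Machine learning of adiabatic potential energy surfaces in the
    vicinity of conical intersection seams. Instead of fitting the
    non-differentiable adiabatic energies directly, the package learns the
    average adiabatic energy and the coefficients of the characteristic
    polynomial of the traceless splitting matrix, which are smooth functions
    of nuclear coordinates even across intersection seams. Adiabatic
    potentials are recovered as eigenvalues of a companion matrix, and the
    branching-space dimensionality and cone topography (orthogonalized
    gradient-difference and derivative-coupling norms, tilt parameters) are
    extracted from the Hessian of a single polynomial coefficient. Includes
    analytic linear vibronic coupling models and Latin hypercube samplers as
    ground truth, kernel ridge regression with RBF and Matern-1/2 kernels, a
    reduced power-spectrum descriptor for molecular Cartesian geometries,
    dataset and model serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'cp-core.R'
    'model-potentials.R'
    'sampling.R'
    'spherical-harmonics.R'
    'descriptors.R'
    'krr.R'
    'ensemble.R'
    'topography.R'
    'meci.R'
    'io-dataset.R'
    'io-ensemble.R'
    'config.R'
    'cli.R'
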