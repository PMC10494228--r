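# Kernel ridge regression of the smooth fields and the two model families.

test_that("kernel entries match their closed forms", {
  x <- matrix(c(0, 0), 1, 2)
  expect_equal(kernelMatrix("rbf", x, x, 1)[1, 1], 1)
  expect_equal(kernelMatrix("matern12", x, x, 1)[1, 1], 1)
  a <- matrix(c(0, 0), 1, 2)
  b <- matrix(c(sqrt(2) * 0.7, 0), 1, 2)   # distance = lengthscale*sqrt(2)
  expect_equal(kernelMatrix("rbf", a, b, 0.7)[1, 1], exp(-1))
  d <- matrix(c(0.3, 0), 1, 2)             # distance = lengthscale
  expect_equal(kernelMatrix("matern12", a, d, 0.3)[1, 1], exp(-1))
  expect_error(kernelMatrix("rbf", a, b, 0), class = "omegaCP_input_error")
})

test_that("kernel Gram matrices are positive semidefinite", {
  set.seed(17)
  for (kind in c("rbf", "matern12")) {
    X <- matrix(rnorm(60), 20, 3)
    K <- kernelMatrix(kind, X, X, 0.8)
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("KRR interpolates training targets at tiny regularization", {
  set.seed(3)
  X <- matrix(seq(-1, 1, length.out = 20), ncol = 1)
  y <- X[, 1]^2
  m <- fitKRR(X, y, "rbf", lengthscale = 0.5, regularization = 1e-12)
  expect_lt(max(abs(predictKRR(m, X) - y)), 1e-6)
  # constant targets: exact at the training points, decaying toward zero
  # far outside the data (the kernel-reach argument for learning slowly
  # varying fields)
  mc <- fitKRR(X, rep(2, 20), "rbf", 0.5, 1e-12)
  expect_equal(predictKRR(mc, X), rep(2, 20), tolerance = 1e-6)
  expect_lt(abs(predictKRR(mc, matrix(50))), 1e-6)
  expect_lt(abs(predictKRR(m, matrix(50))), 1e-6)
})

test_that("singular systems at zero regularization give an actionable error", {
  X <- matrix(c(1, 1, 2), ncol = 1)[c(1, 1, 3), , drop = FALSE]
  err <- tryCatch(fitKRR(X, c(1, 1, 2), "rbf", 1, 0), error = identity)
  expect_s3_class(err, "omegaCP_numerical_error")
  expect_match(conditionMessage(err), "regularization")
})

test_that("hyperparameter grid search is seeded and tie-broken deterministically", {
  set.seed(12)
  X <- matrix(runif(200, -1, 1), ncol = 2)
  y <- 0.3 * X[, 1] - 0.7 * X[, 2]
  one <- selectHyperparams(X, y, 0.5, 1e-8, folds = 4, seed = 2)
  expect_equal(one$lengthscale, 0.5)
  expect_equal(one$regularization, 1e-8)
  sel1 <- selectHyperparams(X, y, c(0.5, 1, 2), c(1e-10, 1e-6),
                            folds = 4, seed = 2)
  sel2 <- selectHyperparams(X, y, c(0.5, 1, 2), c(1e-10, 1e-6),
                            folds = 4, seed = 2)
  expect_identical(sel1[c("lengthscale", "regularization")],
                   sel2[c("lengthscale", "regularization")])
  # noiseless smooth target: some grid point reaches near-zero CV MAE
  expect_lt(min(sel1$cvMAE$mae), 1e-3)
  expect_error(selectHyperparams(X, y, numeric(0), 1e-8),
               class = "omegaCP_input_error")
  expect_error(selectHyperparams(X[1:3, ], y[1:3], 1, 1e-8, folds = 5),
               class = "omegaCP_input_error")
})

test_that("fitEnsemble builds one model per learned field in each mode", {
  m <- referenceTwoState()
  ds <- simulateDataset(m, 60, c(-0.25, 0.25), seed = 21)
  e1 <- fitEnsemble(ds, mode = "omega_cp")
  expect_identical(names(componentModels(e1)), c("omega", "c0"))
  e2 <- fitEnsemble(ds, mode = "direct")
  expect_identical(names(componentModels(e2)), c("E1", "E2"))

  m3 <- randomLinearVibronic(3, 4, 3, seed = 3)
  ds3 <- simulateDataset(m3, 80, c(-0.25, 0.25), seed = 22)
  e3 <- fitEnsemble(ds3, mode = "omega_cp")
  expect_identical(names(componentModels(e3)), c("omega", "c0", "c1"))
  e4 <- fitEnsemble(ds3, mode = "direct")
  expect_identical(names(componentModels(e4)), c("E1", "E2", "E3"))
})

test_that("surrogates reproduce training energies at training points", {
  m <- referenceTwoState()
  ds <- simulateDataset(m, 80, c(-0.25, 0.25), seed = 31)
  # the nonsmooth direct targets need a sharper lengthscale to keep the
  # near-singular interpolation system well conditioned
  for (setup in list(list(mode = "omega_cp", ls = 0.2),
                     list(mode = "direct", ls = 0.05))) {
    ens <- fitEnsemble(ds, mode = setup$mode,
                       hyper = list(lengthscale = setup$ls,
                                    regularization = 1e-12))
    i <- c(1L, 40L, 80L)
    pred <- predictEnergies(ens, coords(ds)[i, ])
    expect_lt(max(abs(pred - energies(ds)[i, ])), 1e-6)
  }
})

test_that("training targets are representation independent", {
  # energies handed back from a rotated electronic basis are the same
  # eigenvalues, so the (omega, c_i) targets cannot change; the matrix-level
  # oracle certifies the underlying invariance
  set.seed(43)
  m <- randomLinearVibronic(3, 4, 3, seed = 10)
  x <- runif(4, -0.2, 0.2)
  V <- matrix(0, 3, 3)
  for (k in 1:4) V <- V + x[k] * m@couplings[[k]]
  V <- V + sum(m@tilt * x) * diag(3)
  Q <- randomOrthogonal(3)
  expect_true(cpInvarianceCheck(V, Q))
  Ead <- energies(evaluateModel(m, x))
  Erot <- sort(eigen(t(Q) %*% V %*% Q, symmetric = TRUE)$values)
  r1 <- energiesToCP(Ead); r2 <- energiesToCP(Erot)
  expect_equal(omega(r1), omega(r2), tolerance = 1e-12)
  expect_equal(cpCoeffs(r1), cpCoeffs(r2), tolerance = 1e-10)
})

test_that("learning curve decreases with size; smooth fields beat direct near the seam", {
  m <- referenceTwoState()
  test <- simulateDataset(m, 120, c(-0.05, 0.05), seed = 99)  # near the seam
  sizes <- c(30L, 120L)
  cvCP <- maeCurve(m, sizes, test, mode = "omega_cp", seed = 1)
  cvD  <- maeCurve(m, sizes, test, mode = "direct", seed = 1)
  maeBySize <- function(cv) tapply(cv$mae, cv$size, mean)
  expect_lte(maeBySize(cvCP)[["120"]], maeBySize(cvCP)[["30"]])
  expect_lt(maeBySize(cvCP)[["120"]], maeBySize(cvD)[["120"]])
  expect_error(maeCurve(m, c(50L, 20L), test), class = "omegaCP_input_error")
})
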