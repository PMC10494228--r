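# Analytic linear vibronic models and the Latin hypercube sampler.

test_that("two-state branching-plane model matches its closed form", {
  m <- referenceTwoState()
  expect_equal(energies(evaluateModel(m, c(0, 0))), c(0, 0))
  expect_equal(energies(evaluateModel(m, c(1, 0))), c(-0.25, 0.75))
  # c0 field is -(g^2 x^2 + h^2 y^2)
  f <- scalarFields(m)
  expect_equal(f$cnm2(c(1, 1)), -0.5)
  expect_equal(f$cnm2(c(0.3, -0.2)), -(0.25 * 0.09 + 0.25 * 0.04))
  # gap is 2 sqrt(g^2 x^2 + h^2 y^2); zero only at the origin
  gap <- function(x) diff(energies(evaluateModel(m, x)))
  expect_equal(gap(c(0.2, 0.1)), 2 * sqrt(0.25 * 0.04 + 0.25 * 0.01))
  expect_gt(gap(c(1e-3, 0)), 0)
  expect_error(firstOrderTwoState(0, 0.5), class = "omegaCP_input_error")
  expect_error(firstOrderTwoState(0.5, -1), class = "omegaCP_input_error")
})

test_that("model energies mirror about the tilt term under x -> -x", {
  m <- ethyleneLikeTwoState()
  p <- c(0.11, -0.07)
  Ep <- energies(evaluateModel(m, p))
  Em <- energies(evaluateModel(m, -p))
  tilt <- sum(m@tilt * p)
  # splitting part is even in the coordinates, tilt part is odd
  expect_equal(Ep - tilt, Em + tilt, tolerance = 1e-12)
})

test_that("random models span exactly the requested branching rank", {
  m <- randomLinearVibronic(3, 7, 5, seed = 4)
  H <- omegaCP:::lvcBranchingHessian(m)
  sp <- splitBranchingSeam(H, relativeThreshold = 1e-3)
  expect_identical(sp$branchingDim, 5L)          # five for a 3-state CI
  expect_equal(sum(abs(sp$seam$values) < 1e-12), 2L)

  m2 <- randomLinearVibronic(2, 5, 2, seed = 9)
  H2 <- omegaCP:::lvcBranchingHessian(m2)
  ev <- eigen(H2, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(ev == 0), 3L)             # dim - rank exact zeros
  # all states degenerate at the origin
  expect_equal(diff(range(energies(evaluateModel(m2, numeric(5))))), 0)

  expect_error(randomLinearVibronic(2, 5, 4, seed = 1),
               class = "omegaCP_input_error")    # rank > n(n+1)/2 - 1
  expect_error(randomLinearVibronic(3, 2, 5, seed = 1),
               class = "omegaCP_input_error")    # rank > dim
})

test_that("rank-2 two-state random model is structurally a branching-plane model", {
  m <- randomLinearVibronic(2, 2, 2, seed = 13)
  # couplings are scaled versions of the off-diagonal and diagonal-difference
  # generators: an axis-swapped first-order two-state model
  W1 <- m@couplings[[1]]; W2 <- m@couplings[[2]]
  expect_equal(W1, W1[1, 2] * matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(W2, W2[1, 1] * diag(c(1, -1)))
  h <- abs(W1[1, 2]); g <- abs(W2[1, 1])
  E <- energies(evaluateModel(m, c(0.2, -0.1)))
  tilt <- sum(m@tilt * c(0.2, -0.1))
  expect_equal(E, tilt + c(-1, 1) * sqrt(h^2 * 0.04 + g^2 * 0.01))
})

test_that("same seed reproduces the same model; evaluation checks input", {
  expect_equal(randomLinearVibronic(3, 6, 4, seed = 2)@couplings,
               randomLinearVibronic(3, 6, 4, seed = 2)@couplings)
  m <- referenceTwoState()
  expect_error(evaluateModel(m, c(1, 2, 3)), class = "omegaCP_input_error")
  expect_error(evaluateModel(m, c(1, NA)), class = "omegaCP_input_error")
})

test_that("finite-difference Hessians of the exact c0 field converge at O(step^2)", {
  # quartic perturbation makes the field non-quadratic so truncation error
  # is visible and must shrink ~4x when the step halves
  f <- function(x) -(0.3 * x[1]^2 + 0.2 * x[2]^2) + 0.5 * x[1]^4 + x[2]^4
  Href <- diag(c(-0.6, -0.4))
  e1 <- max(abs(hessianCnm2(f, c(0, 0), 0.2) - Href))
  e2 <- max(abs(hessianCnm2(f, c(0, 0), 0.1) - Href))
  expect_gt(e1 / e2, 3.5)
  expect_lt(e1 / e2, 4.5)
  # analytic branching Hessian of the reference model, via exact fields
  m <- referenceTwoState()
  H <- hessianCnm2(scalarFields(m)$cnm2, c(0, 0), 1e-3)
  expect_equal(H, diag(c(-0.5, -0.5)), tolerance = 1e-9)  # -2g^2, -2h^2
})

test_that("latin hypercube stratifies every 1D projection", {
  X <- latinHypercube(1, 4, c(0, 1), seed = 3)
  bins <- findInterval(X[, 1], c(0, 0.25, 0.5, 0.75, 1), rightmost.closed = TRUE)
  expect_setequal(bins, 1:4)

  X2 <- latinHypercube(2, 100, c(-0.25, 0.25), seed = 3)
  expect_true(all(X2 >= -0.25 & X2 <= 0.25))
  for (k in 1:2) {
    bins <- floor((X2[, k] + 0.25) / 0.5 * 100)
    expect_setequal(pmin(bins, 99), 0:99)  # one point per bin
  }
  expect_identical(latinHypercube(3, 17, c(-1, 2), seed = 8),
                   latinHypercube(3, 17, c(-1, 2), seed = 8))
  expect_error(latinHypercube(2, 10, c(1, 1), seed = 1),
               class = "omegaCP_input_error")
})

test_that("makeDataset evaluates rows faithfully and records provenance", {
  m <- referenceTwoState()
  expect_identical(nSamples(makeDataset(m, matrix(0, 0, 2))), 0L)
  X <- latinHypercube(2, 25, c(-0.25, 0.25), seed = 5)
  ds <- makeDataset(m, X)
  expect_identical(nSamples(ds), 25L)
  for (i in c(1L, 13L, 25L))
    expect_identical(energies(ds)[i, ],
                     structure(energies(evaluateModel(m, X[i, ])),
                               names = c("E1", "E2")))
  ds2 <- simulateDataset(m, 30, c(-0.25, 0.25), seed = 6)
  expect_identical(provenance(ds2)$generator, "latinHypercube")
  expect_identical(provenance(ds2)$seed, 6)
})

test_that("optional label noise perturbs energies but keeps them sorted", {
  m <- referenceTwoState()
  X <- latinHypercube(2, 40, c(-0.25, 0.25), seed = 2)
  clean <- makeDataset(m, X)
  noisy <- makeDataset(m, X, noiseSd = 1e-3, seed = 77)
  expect_false(identical(energies(clean), energies(noisy)))
  expect_true(all(apply(energies(noisy), 1, function(e) !is.unsorted(e))))
  expect_lt(max(abs(energies(clean) - energies(noisy))), 6e-3)
  expect_error(makeDataset(m, X, noiseSd = 1e-3),
               class = "omegaCP_input_error")   # seed required
})
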