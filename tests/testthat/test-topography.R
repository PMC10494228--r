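# Branching/seam analysis and cone topography.

test_that("central-difference Hessian is exact on quadratics and zero on constants", {
  f <- function(x) -(0.7 * x[1]^2 + 0.2 * x[2]^2) + 0.5 * x[1] * x[2]
  H <- hessianCnm2(f, c(0.3, -0.4), 1e-2)
  expect_equal(H, matrix(c(-1.4, 0.5, 0.5, -0.4), 2, 2), tolerance = 1e-9)
  expect_equal(hessianCnm2(function(x) 3.2, c(0, 0), 1e-3), matrix(0, 2, 2))
  expect_error(hessianCnm2(f, c(0, 0), step = 0),
               class = "omegaCP_input_error")
})

test_that("branching/seam split counts eigenvalues against the relative threshold", {
  H <- diag(c(-0.5, -0.5, 0, 0, 0))
  sp <- splitBranchingSeam(H)
  expect_identical(sp$branchingDim, 2L)
  expect_identical(ncol(sp$seam$vectors), 3L)
  expect_equal(crossprod(sp$branching$vectors), diag(2))
  # tiny noise below threshold is all seam; an exactly zero matrix has no
  # branching directions at all
  spN <- splitBranchingSeam(diag(c(-1, -1e-5, 1e-6)), relativeThreshold = 1e-2)
  expect_identical(spN$branchingDim, 1L)
  sp0 <- splitBranchingSeam(matrix(0, 3, 3))
  expect_identical(sp0$branchingDim, 0L)
  expect_error(splitBranchingSeam(matrix(1:6, 2, 3)),
               class = "omegaCP_input_error")
})

test_that("branching dimension equals the constructed rank across n and dim", {
  cases <- list(c(2, 2, 2), c(2, 5, 2), c(2, 8, 2),
                c(3, 3, 3), c(3, 5, 5), c(3, 7, 5), c(3, 8, 4))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    m <- randomLinearVibronic(cs[1], cs[2], cs[3], seed = 100 + i)
    H <- hessianCnm2(scalarFields(m)$cnm2, numeric(cs[2]), 1e-3)
    # noiseless analytic Hessians: threshold well below the smallest
    # possible coupling eigenvalue, far above finite-difference rounding
    sp <- splitBranchingSeam(H, relativeThreshold = 1e-3)
    expect_identical(sp$branchingDim, as.integer(cs[3]))
    expect_equal(H, omegaCP:::lvcBranchingHessian(m), tolerance = 1e-7)
  }
})

test_that("branching dimension is threshold-robust on reference-scale models", {
  for (m in list(referenceTwoState(), ethyleneLikeTwoState())) {
    H <- hessianCnm2(scalarFields(m)$cnm2, c(0, 0), 1e-3)
    dims <- vapply(c(1e-3, 1e-2, 5e-2, 1e-1),
                   function(th) splitBranchingSeam(H, th)$branchingDim,
                   integer(1))
    expect_true(all(dims == 2L))
  }
})

test_that("cone parameters recover the reference and ethylene-like values", {
  rep1 <- coneParameters(referenceTwoState(), c(0, 0))
  expect_equal(coneTopography(rep1),
               c(g = 0.5, h = 0.5, s_x = 0.25, s_y = 0.1), tolerance = 1e-8)
  expect_identical(branchingDim(rep1), 2L)

  rep2 <- coneParameters(ethyleneLikeTwoState(), c(0, 0))
  expect_equal(coneTopography(rep2),
               c(g = 0.213, h = 0.125, s_x = -0.130, s_y = -0.046),
               tolerance = 1e-8)
  # untilted symmetric cone: tilts vanish
  rep3 <- coneParameters(firstOrderTwoState(0.342, 0.342), c(0, 0))
  expect_lt(abs(rep3@sX), 1e-8)
  expect_lt(abs(rep3@sY), 1e-8)
  expect_equal(rep3@gNorm, 0.342, tolerance = 1e-8)

  # three-state branching space has dimension 5: no two-state cone there
  m3 <- randomLinearVibronic(3, 7, 5, seed = 4)
  expect_error(coneParameters(m3, numeric(7)), class = "omegaCP_input_error")
})

test_that("cone parameters are recovered across random two-state models", {
  # analytic fields: exact recovery (g >= h ordering, tilts follow the
  # reordering of the branching axes)
  set.seed(55)
  for (i in 1:50) {
    g <- runif(1, 0.05, 0.6); h <- runif(1, 0.05, 0.6)
    tl <- runif(2, -0.3, 0.3)
    m <- firstOrderTwoState(g, h, tl[1], tl[2])
    rp <- coneParameters(m, c(0, 0))
    # the c0 Hessian is exactly diagonal, so each branching vector is a
    # (positively signed) coordinate axis; read the axis order from the
    # report — for a near-symmetric cone it is a convention, not physics
    i1 <- which.max(abs(branchingVectors(rp)[, 1]))
    i2 <- which.max(abs(branchingVectors(rp)[, 2]))
    expect_identical(sort(c(i1, i2)), 1:2)
    expect_equal(coneTopography(rp),
                 c(g = max(g, h), h = min(g, h),
                   s_x = tl[i1], s_y = tl[i2]), tolerance = 1e-6)
    if (abs(g - h) > 0.01 * max(g, h))   # unambiguous ordering: x is steeper
      expect_identical(i1, which.max(c(g, h)))
  }
})

test_that("surrogate cone parameters match the analytic ones to ~2%", {
  # three representative models (runtime keeps the full 50-model sweep out
  # of the default suite); 2000-point training sets as in the headline fits
  params <- list(c(0.5, 0.5, 0.25, 0.1),
                 c(0.213, 0.125, -0.130, -0.046),
                 c(0.342, 0.342, 0, 0))
  for (i in seq_along(params)) {
    p <- params[[i]]
    m <- firstOrderTwoState(p[1], p[2], p[3], p[4])
    ds <- simulateDataset(m, 2000, c(-0.25, 0.25), seed = 300 + i)
    ens <- fitEnsemble(ds)
    rp <- coneParameters(ens, c(0, 0))
    expect_equal(rp@gNorm, max(p[1:2]), tolerance = 0.02)
    expect_equal(rp@hNorm, min(p[1:2]), tolerance = 0.02)
    expect_equal(abs(rp@sX), max(abs(p[3:4])), tolerance = 0.02)
    expect_equal(abs(rp@sY), min(abs(p[3:4])), tolerance = 0.02)
    # branching plane agrees with the analytic one at subspace level
    ref <- coneParameters(m, c(0, 0))
    expect_lt(max(principalAngles(branchingVectors(rp),
                                  branchingVectors(ref))), 0.5)
  }
})

test_that("orthogonalization of nascent g/h vectors", {
  # already orthogonal input: unchanged up to ordering
  res <- orthogonalizeGH(c(2, 0, 0), c(0, 1, 0))
  expect_equal(res$x, c(1, 0, 0))
  expect_equal(res$y, c(0, 1, 0))
  expect_equal(c(res$gNorm, res$hNorm), c(2, 1))
  # parallel input degenerates to a single direction
  resP <- orthogonalizeGH(c(1, 1), c(1, 1))
  expect_lt(resP$hNorm, 1e-12)
  expect_equal(resP$gNorm, 2)
  expect_error(orthogonalizeGH(c(0, 0), c(0, 0)),
               class = "omegaCP_input_error")
  # random pairs: outputs orthogonal, span preserved
  set.seed(77)
  for (i in 1:20) {
    g <- rnorm(4); h <- rnorm(4)
    r <- orthogonalizeGH(g, h)
    expect_lt(abs(sum(r$x * r$y)), 1e-10)
    B <- cbind(r$x, r$y)
    resid <- cbind(g, h) - B %*% crossprod(B, cbind(g, h))
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("principal angles compare subspaces, not individual vectors", {
  A <- diag(4)[, 1:2]
  expect_equal(principalAngles(A, A), c(0, 0))
  expect_equal(principalAngles(A, diag(4)[, 3:4]), c(90, 90))
  th <- 10 * pi / 180   # in-plane rotation preserves the span
  B <- A %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  # acos is ill-conditioned near 1: angles resolve to ~1e-6 degrees
  expect_lt(max(principalAngles(A, B)), 1e-4)
  expect_error(principalAngles(A, diag(3)[, 1:2]),
               class = "omegaCP_input_error")
})

test_that("gap scans find the intersection of the analytic model", {
  m <- referenceTwoState()
  line <- cbind(seq(-0.2, 0.2, length.out = 81), 0)
  sc <- gapScan(m, line)
  expect_equal(sc$minGap, 0)
  expect_equal(sc$minGapPoint, c(0, 0))
  expect_identical(dim(sc$energies), c(81L, 2L))
})

test_that("penalty-method MECI search converges to the intersection", {
  m <- referenceTwoState()
  res <- locateMECI(m, c(0.1, 0.1), tolerance = 1e-5)
  expect_true(res$converged)
  expect_lt(sqrt(sum(res$point^2)), 1e-4)
  # starting at the intersection: immediate convergence
  res0 <- locateMECI(m, c(0, 0), tolerance = 1e-6)
  expect_true(res0$converged)
  # tilted model with a genuine 1D seam in 3 coordinates: two branching
  # coordinates plus one pure seam direction
  m3 <- randomLinearVibronic(2, 3, 2, seed = 8)
  res3 <- locateMECI(m3, c(0.05, -0.04, 0.08), tolerance = 1e-5)
  expect_lte(res3$gap, 1e-5)
})
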