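## Analytic linear vibronic coupling models: the minimal potentials that
## exhibit a conical intersection, used both as ground truth for the
## surrogate pipeline and as the data generator standing in for ab initio
## training sets.

#' First-order model of a two-state conical intersection
#'
#' The standard branching-plane model
#' \deqn{V(x, y) = (s_x x + s_y y) I +
#'   \begin{pmatrix} \tilde g x & \tilde h y \\ \tilde h y & -\tilde g x
#'   \end{pmatrix}}
#' with adiabatic energies
#' \eqn{s_x x + s_y y \pm \sqrt{\tilde g^2 x^2 + \tilde h^2 y^2}}: a double
#' cone touching at the origin, with pitch set by \eqn{\tilde g, \tilde h}
#' and tilt by \eqn{s_x, s_y}.
#'
#' @param gNorm,hNorm positive pitch norms (E_h per coordinate unit): the
#'   norms of the orthogonalized gradient-difference and derivative-coupling
#'   vectors.
#' @param sX,sY tilt parameters (E_h per coordinate unit).
#' @return a \linkS4class{LinearVibronicModel} with \code{dim = 2},
#'   \code{nStates = 2}.
#' @examples
#' m <- firstOrderTwoState(0.5, 0.5, 0.25, 0.1)
#' energies(evaluateModel(m, c(1, 0)))  # -0.25, 0.75
#' @export
firstOrderTwoState <- function(gNorm, hNorm, sX = 0, sY = 0) {
  if (!is.numeric(gNorm) || length(gNorm) != 1L || !is.finite(gNorm) ||
      gNorm <= 0 || !is.numeric(hNorm) || length(hNorm) != 1L ||
      !is.finite(hNorm) || hNorm <= 0)
    stopInput("gNorm and hNorm must be single positive numbers")
  new("LinearVibronicModel", nStates = 2L, dim = 2L, tilt = c(sX, sY),
      couplings = list(gNorm * diag(c(1, -1)),
                       hNorm * matrix(c(0, 1, 1, 0), 2, 2)))
}

## Deterministic basis of the traceless symmetric n x n space: off-diagonal
## generators first (i < j, column-major order), then the n - 1 adjacent
## diagonal differences. Linearly independent; off-diagonals are mutually
## Frobenius-orthogonal.
tracelessSymmetricBasis <- function(n) {
  basis <- list()
  for (j in 2:n) for (i in 1:(j - 1L)) {
    B <- matrix(0, n, n); B[i, j] <- B[j, i] <- 1
    basis[[length(basis) + 1L]] <- B
  }
  for (k in 1:(n - 1L)) {
    B <- matrix(0, n, n); B[k, k] <- 1; B[k + 1L, k + 1L] <- -1
    basis[[length(basis) + 1L]] <- B
  }
  basis
}

#' Random linear vibronic model with a prescribed branching rank
#'
#' Builds an n-state model in \code{dim} coordinates whose coupling matrices
#' span exactly \code{branchingRank} dimensions of the traceless symmetric
#' matrix space: the first \code{branchingRank} coordinates carry independent
#' basis matrices scaled by random coefficients in [0.1, 1], the remaining
#' coordinates carry zero coupling and are therefore pure seam directions at
#' the origin. A two-state intersection admits rank 2 (branching plane); a
#' three-state intersection admits up to rank 5.
#'
#' @param nStates number of electronic states (>= 2).
#' @param dim number of nuclear coordinates (>= branchingRank).
#' @param branchingRank requested branching dimension, at most
#'   \code{min(dim, nStates (nStates + 1) / 2 - 1)}.
#' @param seed integer seed; identical seeds give identical models.
#' @param tiltRange half-width of the uniform tilt draw (default 0.1).
#' @return a \linkS4class{LinearVibronicModel}.
#' @export
randomLinearVibronic <- function(nStates, dim, branchingRank, seed,
                                 tiltRange = 0.1) {
  nStates <- as.integer(nStates); dim <- as.integer(dim)
  branchingRank <- as.integer(branchingRank)
  maxRank <- min(dim, (nStates * (nStates + 1L)) %/% 2L - 1L)
  if (nStates < 2L) stopInput("nStates must be >= 2")
  if (branchingRank < 1L || branchingRank > maxRank)
    stopInput("branchingRank %d infeasible: must be in [1, %d] for n = %d, dim = %d",
              branchingRank, maxRank, nStates, dim)
  withSeed(seed, {
    basis <- tracelessSymmetricBasis(nStates)
    coef <- stats::runif(branchingRank, 0.1, 1.0)
    tilt <- stats::runif(dim, -tiltRange, tiltRange)
    couplings <- vector("list", dim)
    for (k in seq_len(dim)) {
      couplings[[k]] <- if (k <= branchingRank) coef[k] * basis[[k]]
        else matrix(0, nStates, nStates)
    }
    new("LinearVibronicModel", nStates = nStates, dim = dim, tilt = tilt,
        couplings = couplings)
  })
}

#' @describeIn evaluateModel eigen-decomposition of the linear potential
#'   matrix \eqn{(\mathrm{tilt}\cdot x) I + \sum_k x_k W_k}.
setMethod("evaluateModel", "LinearVibronicModel", function(model, coords, ...) {
  if (!is.numeric(coords) || length(coords) != model@dim)
    stopInput("coords must have length %d, got %d", model@dim, length(coords))
  if (anyNA(coords) || any(!is.finite(coords)))
    stopInput("coords must be finite")
  n <- model@nStates
  M <- matrix(0, n, n)
  for (k in seq_len(model@dim))
    if (coords[k] != 0) M <- M + coords[k] * model@couplings[[k]]
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  new("PotentialSample", coords = as.numeric(coords),
      energies = ev + sum(model@tilt * coords))
})

#' Scalar fields of a model or surrogate
#'
#' Returns closures evaluating the average adiabatic energy and the
#' branching coefficient \eqn{c_{n-2}} at a coordinate vector. For an
#' analytic model the fields are exact; for a fitted ensemble in
#' \code{"omega_cp"} mode they are the corresponding component regressors,
#' and in \code{"direct"} mode they are computed from the predicted energies.
#'
#' @param object a \linkS4class{LinearVibronicModel} or
#'   \linkS4class{SurrogateEnsemble}.
#' @return list with elements \code{omega} and \code{cnm2}, each a
#'   function(coords) -> numeric(1).
#' @export
scalarFields <- function(object) {
  if (is(object, "LinearVibronicModel")) {
    list(
      omega = function(x) mean(energies(evaluateModel(object, x))),
      cnm2  = function(x) gapSumIdentity(energies(evaluateModel(object, x))))
  } else if (is(object, "SurrogateEnsemble")) {
    if (identical(object@mode, "omega_cp")) {
      omegaModel <- object@models[["omega"]]
      cModel <- object@models[[paste0("c", object@nStates - 2L)]]
      list(
        omega = function(x) predictKRR(omegaModel, .featurizePoint(object, x)),
        cnm2  = function(x) predictKRR(cModel, .featurizePoint(object, x)))
    } else {
      list(
        omega = function(x) mean(predictEnergies(object, x)),
        cnm2  = function(x) gapSumIdentity(predictEnergies(object, x)))
    }
  } else stopInput("no scalar fields for class '%s'", class(object))
}

## Analytic Gram-matrix Hessian of c_{n-2} at the origin of a linear
## vibronic model: since sum_{i<j} dE_ij^2 = n tr(M^2) for the traceless
## M = sum_k x_k W_k, c_{n-2}(x) = -(1/2) sum_kl x_k x_l tr(W_k W_l) exactly,
## so the Hessian is minus the Frobenius Gram matrix of the couplings.
lvcBranchingHessian <- function(model) {
  d <- model@dim
  H <- matrix(0, d, d)
  for (k in seq_len(d)) for (l in k:d) {
    H[k, l] <- H[l, k] <- -sum(model@couplings[[k]] * model@couplings[[l]])
  }
  H
}
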