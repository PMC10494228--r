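## Branching/seam analysis at a conical intersection. All branching-space
## information lives in the single coefficient c_{n-2} = -(1/2n) sum dE^2:
## its Hessian at an intersection point has a column space equal to the
## branching space (negative eigenvalues -2g^2, -2h^2 in the two-state
## case) and a null space equal to the seam space.

#' Central-difference Hessian of a scalar field
#'
#' Second-order accurate stencil: diagonal entries from the 3-point second
#' difference, off-diagonal entries from the 4-point cross stencil; the
#' result is explicitly symmetrized as (B + t(B))/2. Exact (up to rounding)
#' on quadratic fields.
#'
#' @param field function(coords) -> numeric(1).
#' @param point numeric coordinate vector.
#' @param step finite-difference step (> 0), default 1e-3 coordinate units.
#' @return symmetric numeric matrix d x d.
#' @export
hessianCnm2 <- function(field, point, step = 1e-3) {
  if (!is.function(field)) stopInput("'field' must be a function")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stopInput("step must be a single positive number")
  d <- length(point)
  H <- matrix(0, d, d)
  f0 <- field(point)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, step)
    H[i, i] <- (field(point + ei) - 2 * f0 + field(point - ei)) / step^2
    if (i < d) for (j in (i + 1L):d) {
      ej <- replace(numeric(d), j, step)
      H[i, j] <- H[j, i] <-
        (field(point + ei + ej) - field(point + ei - ej) -
         field(point - ei + ej) + field(point - ei - ej)) / (4 * step^2)
    }
  }
  (H + t(H)) / 2
}

## Central-difference gradient, same stencil order as the Hessian.
.centralGradient <- function(field, point, step) {
  d <- length(point)
  g <- numeric(d)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, step)
    g[i] <- (field(point + ei) - field(point - ei)) / (2 * step)
  }
  g
}

#' Split a Hessian spectrum into branching and seam eigenpairs
#'
#' Eigenvalues with \eqn{|\lambda| \ge} \code{relativeThreshold}
#' \eqn{\cdot \max|\lambda|} are branching; the rest span the seam space.
#' Eigenpairs are ordered by descending magnitude with a deterministic sign
#' convention (first nonzero component positive). Within a degenerate
#' branching cluster (equal eigenvalues, e.g. a symmetric cone with
#' \eqn{\tilde g = \tilde h}) individual eigenvectors are arbitrary up to
#' rotation; the cluster basis is canonicalized by Gram-Schmidt on the
#' projections of the coordinate axes onto the cluster subspace.
#'
#' @param hessian symmetric numeric matrix.
#' @param relativeThreshold relative magnitude cutoff (default 1e-2);
#'   surrogate Hessians are never exactly zero along the seam.
#' @param degeneracyTol eigenvalues within this relative distance of each
#'   other form a degenerate cluster (default 1e-3). Surrogate Hessians of
#'   a symmetric cone are never exactly degenerate, yet their eigenvectors
#'   are already arbitrary once the eigenvalue gap falls below the fitting
#'   error, so clustering must be tolerant.
#' @return list with elements \code{branching} and \code{seam}, each a list
#'   of \code{values} (numeric) and \code{vectors} (orthonormal columns),
#'   plus \code{branchingDim}.
#' @export
splitBranchingSeam <- function(hessian, relativeThreshold = 1e-2,
                               degeneracyTol = 1e-3) {
  if (!is.matrix(hessian) || nrow(hessian) != ncol(hessian))
    stopInput("'hessian' must be square")
  if (max(abs(hessian - t(hessian))) >
      1e-8 * max(1, max(abs(hessian))))
    stopInput("'hessian' must be symmetric")
  d <- nrow(hessian)
  eig <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  maxAbs <- max(abs(vals))
  isBranch <- if (maxAbs == 0) rep(FALSE, d) else
    abs(vals) >= relativeThreshold * maxAbs
  ## canonicalize degenerate clusters among the branching eigenpairs
  if (any(isBranch)) {
    bIdx <- which(isBranch)
    cl <- split(bIdx, cumsum(c(1, abs(diff(vals[bIdx])) >
                                  degeneracyTol * maxAbs)))
    for (cluster in cl) {
      if (length(cluster) < 2L) next
      vecs[, cluster] <- .canonicalBasis(vecs[, cluster, drop = FALSE])
    }
  }
  ## sign convention: largest-magnitude component positive (first index on
  ## ties). Robust for fitted Hessians, where the first nonzero component
  ## can be an arbitrarily signed regression residual.
  for (k in seq_len(d)) {
    if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
  }
  list(branching = list(values = vals[isBranch],
                        vectors = vecs[, isBranch, drop = FALSE]),
       seam = list(values = vals[!isBranch],
                   vectors = vecs[, !isBranch, drop = FALSE]),
       branchingDim = sum(isBranch))
}

## Deterministic orthonormal basis of the span of V (columns orthonormal):
## Gram-Schmidt on the projections of the canonical axes, taken in order of
## decreasing projection norm (ties by axis index).
.canonicalBasis <- function(V) {
  P <- tcrossprod(V)            # projector onto span(V)
  k <- ncol(V)
  norms <- sqrt(pmax(diag(P), 0))
  ord <- order(-norms, seq_along(norms))
  B <- matrix(0, nrow(V), k)
  got <- 0L
  for (i in ord) {
    v <- P[, i]
    if (got > 0L)
      v <- v - B[, seq_len(got), drop = FALSE] %*%
        crossprod(B[, seq_len(got), drop = FALSE], v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10) {
      got <- got + 1L
      B[, got] <- v / nv
      if (got == k) break
    }
  }
  if (got < k) stopNumerical("failed to canonicalize a degenerate eigenspace")
  B
}

#' Orthogonalize nascent gradient-difference and coupling vectors
#'
#' Rotates the pair (g, h) by the angle \eqn{\beta} with
#' \eqn{\tan 2\beta = 2 g\cdot h / (\|g\|^2 - \|h\|^2)} so the rotated
#' vectors are mutually orthogonal, and returns unit vectors with the
#' larger-norm direction first. The rotated norms are the cone pitch
#' parameters \eqn{\tilde g \ge \tilde h}.
#'
#' @param g,h numeric vectors of equal length, not both zero.
#' @return list with \code{x}, \code{y} (unit vectors; \code{y} is zero if
#'   its rotated norm vanishes, as for parallel input), \code{gNorm},
#'   \code{hNorm}.
#' @export
orthogonalizeGH <- function(g, h) {
  if (length(g) != length(h))
    stopInput("g and h must have the same length")
  ng2 <- sum(g^2); nh2 <- sum(h^2)
  if (ng2 == 0 && nh2 == 0) stopInput("g and h must not both be zero")
  beta <- 0.5 * atan2(2 * sum(g * h), ng2 - nh2)
  gr <- cos(beta) * g + sin(beta) * h
  hr <- -sin(beta) * g + cos(beta) * h
  nG <- sqrt(sum(gr^2)); nH <- sqrt(sum(hr^2))
  if (nH > nG) { tmp <- gr; gr <- hr; hr <- tmp
                 tmp <- nG; nG <- nH; nH <- tmp }
  list(x = if (nG > 1e-12) gr / nG else gr * 0,
       y = if (nH > 1e-12) hr / nH else hr * 0,
       gNorm = nG, hNorm = nH)
}

#' Principal angles between two subspaces
#'
#' Arc-cosines of the singular values of \eqn{A^T B}, in degrees, ascending.
#' Subspace-level comparison is immune to the arbitrary rotation of
#' degenerate eigenvector pairs (a symmetric cone has no preferred x/y).
#'
#' @param A,B matrices with orthonormal columns in the same ambient
#'   dimension.
#' @return numeric vector of \code{min(ncol(A), ncol(B))} angles in degrees.
#' @export
principalAngles <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 1L)
  if (!is.matrix(B)) B <- matrix(B, ncol = 1L)
  if (nrow(A) != nrow(B))
    stopInput("subspaces live in different ambient dimensions (%d vs %d)",
              nrow(A), nrow(B))
  sv <- svd(crossprod(A, B))$d
  sort(acos(pmin(pmax(sv, -1), 1)) * 180 / pi)
}

#' @describeIn coneParameters cone topography from the scalar fields of an
#'   analytic model or fitted surrogate. The Hessian of the branching
#'   coefficient \eqn{c_{n-2}} at \code{ciPoint} is computed by central
#'   differences and split at \code{relativeThreshold}; a two-state
#'   branching plane yields \eqn{\tilde g = \sqrt{-\lambda_1/2}},
#'   \eqn{\tilde h = \sqrt{-\lambda_2/2}} and tilts
#'   \eqn{s_x = \nabla\omega\cdot \hat x}, \eqn{s_y = \nabla\omega\cdot
#'   \hat y}. Errors with an unsupported-topology message when the
#'   branching dimension is not 2, and with an inconsistent-intersection
#'   message when a branching eigenvalue is positive (c_{n-2} <= 0 must
#'   have a local maximum of 0 at the intersection).
#' @param object a \linkS4class{LinearVibronicModel} or fitted
#'   \linkS4class{SurrogateEnsemble}.
#' @param ciPoint coordinates of the intersection point to analyze.
#' @param step central-difference step (default 1e-3).
#' @param relativeThreshold branching/seam eigenvalue cutoff (default 1e-2).
#' @param reference optional matrix of orthonormal columns; if given,
#'   principal angles of the branching space against it are reported.
#' @param ... unused.
setMethod("coneParameters", "ANY",
  function(object, ciPoint, step = 1e-3, relativeThreshold = 1e-2,
           reference = NULL, ...) {
  fields <- scalarFields(object)
  H <- hessianCnm2(fields$cnm2, ciPoint, step)
  sp <- splitBranchingSeam(H, relativeThreshold)
  allVals <- c(sp$branching$values, sp$seam$values)
  if (sp$branchingDim != 2L)
    stopInput(paste0("unsupported topology: branching dimension is %d, ",
                     "cone parameters are defined for two-state ",
                     "intersections (branching dimension 2)"),
              sp$branchingDim)
  lam <- sp$branching$values
  if (any(lam > 1e-8 * max(abs(lam))))
    stopNumerical(paste0("inconsistent intersection: positive branching ",
                         "curvature %.3g (c_{n-2} must have a local maximum ",
                         "of 0 at the intersection)"), max(lam))
  gN <- sqrt(max(-lam[1L], 0) / 2)
  hN <- sqrt(max(-lam[2L], 0) / 2)
  xVec <- sp$branching$vectors[, 1L]
  yVec <- sp$branching$vectors[, 2L]
  gradOmega <- .centralGradient(fields$omega, ciPoint, step)
  ang <- if (is.null(reference)) numeric(0) else
    principalAngles(sp$branching$vectors, reference)
  new("ConeReport", point = as.numeric(ciPoint), hessian = H,
      eigenvalues = allVals, branchingVectors = sp$branching$vectors,
      seamVectors = sp$seam$vectors,
      branchingDim = as.integer(sp$branchingDim),
      gNorm = gN, hNorm = hN,
      sX = sum(gradOmega * xVec), sY = sum(gradOmega * yVec),
      principalAngles = ang)
})

#' Scan adiabatic energies and gaps along a path or grid
#'
#' Evaluates \code{\link{predictEnergies}} at every supplied point and
#' reports the adjacent-state gaps and the location of the minimum gap —
#' the diagnostic separating a true intersection (gap reaching zero) from
#' the avoided crossing a direct-energy fit produces.
#'
#' @param object a \linkS4class{LinearVibronicModel} or
#'   \linkS4class{SurrogateEnsemble}.
#' @param points numeric matrix, one coordinate vector per row.
#' @param states pair of adjacent state indices for the reported minimum
#'   gap (default c(1, 2)).
#' @return list with \code{energies} (matrix), \code{gaps} (matrix of
#'   adjacent differences), \code{minGap}, \code{minGapIndex} and
#'   \code{minGapPoint}.
#' @export
gapScan <- function(object, points, states = c(1L, 2L)) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  E <- predictEnergies(object, points)
  if (!is.matrix(E)) E <- matrix(E, nrow = 1L)
  n <- ncol(E)
  if (any(states < 1L) || any(states > n) || states[2L] != states[1L] + 1L)
    stopInput("states must be a pair of adjacent indices within 1..%d", n)
  gaps <- E[, -1L, drop = FALSE] - E[, -n, drop = FALSE]
  colnames(gaps) <- paste0("gap", seq_len(n - 1L), seq_len(n - 1L) + 1L)
  g <- gaps[, states[1L]]
  i <- which.min(g)
  list(energies = E, gaps = gaps, minGap = g[i], minGapIndex = i,
       minGapPoint = points[i, ])
}
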