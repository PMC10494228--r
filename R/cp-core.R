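## Exact algebra between adiabatic energies and the (omega, CP-coefficient)
## representation.
##
## The potential matrix is decomposed as V = omega I + Z with
## omega = tr(V)/n and Z = diag(E_i - omega) traceless. The coefficients of
## det(lambda I - Z) = lambda^n + c_{n-1} lambda^{n-1} + ... + c_0 are smooth
## functions of geometry even across intersection seams, and they are
## invariant under any orthogonal change of electronic basis — which is the
## whole point of learning them instead of the energies.

#' Convert sorted adiabatic energies to the smooth representation
#'
#' Computes the average energy \eqn{\omega = \bar E} and the coefficients of
#' the characteristic polynomial of the traceless splitting matrix
#' \eqn{Z = \mathrm{diag}(E_i - \omega)} by exact convolution expansion of
#' \eqn{\prod_i (\lambda - z_i)}. The \eqn{\lambda^{n-1}} coefficient must
#' vanish (Z is traceless); it is checked and dropped.
#'
#' @param energies numeric vector of n >= 2 finite adiabatic energies,
#'   ascending (Hartree).
#' @return a \linkS4class{CPRecord}.
#' @examples
#' energiesToCP(c(-1, 1))     # omega = 0, c0 = -1
#' energiesToCP(c(0, 1, 2))   # omega = 1, (c0, c1) = (0, -1)
#' @export
energiesToCP <- function(energies) {
  if (!is.numeric(energies) || length(energies) < 2L)
    stopInput("at least 2 energies are required, got %d", length(energies))
  if (anyNA(energies) || any(!is.finite(energies)))
    stopInput("energies must be finite")
  if (is.unsorted(energies))
    stopInput("energies must be sorted ascending")
  n <- length(energies)
  om <- mean(energies)
  z <- energies - om
  ## monic polynomial coefficients, descending powers: p[1] = 1 (lambda^n)
  p <- 1
  for (zi in z) p <- c(p, 0) - c(0, p * zi)   # multiply by (lambda - zi)
  scale <- max(1, max(abs(energies)))
  cn1 <- p[2L]
  if (abs(cn1) > 1e-12 * scale^1)
    stopNumerical("traceless check failed: |c_{n-1}| = %.3g", abs(cn1))
  ## p = (1, c_{n-1}, c_{n-2}, ..., c_0); keep c_0..c_{n-2} ascending index
  coeffs <- rev(p[-(1:2)])
  new("CPRecord", omega = om, coeffs = coeffs, nStates = n)
}

#' Recover sorted adiabatic energies from a CPRecord
#'
#' Builds the companion matrix of
#' \eqn{\lambda^n + 0\,\lambda^{n-1} + c_{n-2}\lambda^{n-2} + \dots + c_0}
#' and returns its eigenvalues shifted by \eqn{\omega}, sorted ascending.
#' For coefficients produced from a real spectrum the roots are exactly
#' real; eigenvalues with non-negligible imaginary parts signal a record
#' that is not realizable by any real symmetric splitting matrix and raise
#' a numerical-consistency error.
#'
#' @param record a \linkS4class{CPRecord}.
#' @return numeric vector of n energies, ascending (Hartree).
#' @examples
#' cpToEnergies(energiesToCP(c(0, 1, 2)))  # c(0, 1, 2)
#' @export
cpToEnergies <- function(record) {
  if (!is(record, "CPRecord")) stopInput("'record' must be a CPRecord")
  validObject(record)
  res <- companionRoots(record@coeffs, record@nStates)
  if (res$maxRelImag > 1e-8)
    stopNumerical(paste0("companion eigenvalues have imaginary parts ",
                         "(max rel. %.3g): record is not realizable by a ",
                         "real spectrum"), res$maxRelImag)
  sort(res$roots) + record@omega
}

## Roots of lambda^n + c_{n-2} lambda^{n-2} + ... + c_0 via the companion
## matrix; returns real parts and the worst relative imaginary magnitude.
companionRoots <- function(coeffs, n) {
  a <- c(coeffs, 0)                      # (c_0, ..., c_{n-2}, c_{n-1} = 0)
  C <- matrix(0, n, n)
  if (n > 1L) C[cbind(2:n, 1:(n - 1L))] <- 1
  C[, n] <- -a
  ev <- eigen(C, only.values = TRUE)$values
  relImag <- abs(Im(ev)) / pmax(1, abs(Re(ev)))
  list(roots = Re(ev), maxRelImag = max(relImag))
}

#' Squared-gap identity for the branching coefficient
#'
#' Returns \eqn{-\frac{1}{2n}\sum_{i<j}(E_i - E_j)^2}, which equals the
#' characteristic-polynomial coefficient \eqn{c_{n-2}} of the splitting
#' matrix. Because every squared gap rises quadratically along branching
#' directions at an intersection and quartically along seam directions, the
#' Hessian of this single coefficient encodes the whole branching space.
#'
#' @param energies numeric vector of n >= 2 finite energies (Hartree).
#' @return the coefficient value in Hartree^2 (always <= 0; 0 iff all
#'   energies are equal).
#' @examples
#' gapSumIdentity(c(-1, 1))    # -1
#' gapSumIdentity(c(0, 1, 2))  # -1
#' @export
gapSumIdentity <- function(energies) {
  if (!is.numeric(energies) || length(energies) < 2L)
    stopInput("at least 2 energies are required")
  if (anyNA(energies) || any(!is.finite(energies)))
    stopInput("energies must be finite")
  n <- length(energies)
  d <- outer(energies, energies, "-")
  -sum(d[upper.tri(d)]^2) / (2 * n)
}

#' Representation-independence oracle for CP coefficients
#'
#' Checks that the characteristic-polynomial coefficients of the traceless
#' part of a symmetric matrix are unchanged under an orthogonal similarity
#' transform \eqn{Q^T M Q}. This is the property that makes the smooth
#' representation independent of the (arbitrary) choice of electronic basis:
#' adiabatic and diabatic representations give identical coefficients.
#'
#' @param matrix a real symmetric n x n matrix.
#' @param transform an orthogonal n x n matrix (checked to 1e-10).
#' @param tol relative agreement tolerance (default 1e-10).
#' @return TRUE if all coefficients agree to \code{tol}, FALSE otherwise.
#' @export
cpInvarianceCheck <- function(matrix, transform, tol = 1e-10) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stopInput("'matrix' must be square")
  if (max(abs(matrix - t(matrix))) > 1e-10 * max(1, max(abs(matrix))))
    stopInput("'matrix' must be symmetric")
  if (!is.matrix(transform) || !all(dim(transform) == dim(matrix)))
    stopInput("'transform' must match the dimensions of 'matrix'")
  if (max(abs(crossprod(transform) - diag(nrow(transform)))) > 1e-10)
    stopInput("'transform' is not orthogonal to 1e-10")
  c1 <- .symmetricCP(matrix)
  c2 <- .symmetricCP(t(transform) %*% matrix %*% transform)
  all(abs(c1 - c2) <= tol * pmax(1, abs(c1)))
}

## CP coefficients (c_0..c_{n-2}) of the traceless part of a symmetric matrix.
.symmetricCP <- function(M) {
  ev <- sort(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  z <- ev - mean(ev)
  p <- 1
  for (zi in z) p <- c(p, 0) - c(0, p * zi)
  rev(p[-(1:2)])
}
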