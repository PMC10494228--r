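## Minimum-energy conical intersection search on a surrogate (or analytic
## model) by the classic penalty method: minimize the lower-state energy
## plus an increasingly stiff quadratic penalty on the gap. Derivative-free
## (Nelder-Mead), so it applies equally to surrogates fitted to methods
## with no analytic gradients.

#' Locate a minimum-energy conical intersection
#'
#' Minimizes \eqn{E_{\mathrm{lower}} + \sigma\,\Delta E^2} with the penalty
#' weight \eqn{\sigma} increased along \code{penaltySchedule}, restarting
#' each stage from the previous optimum. Convergence requires the final gap
#' to be at or below \code{tolerance}.
#'
#' @param object a two-state \linkS4class{SurrogateEnsemble} or
#'   \linkS4class{LinearVibronicModel}.
#' @param start numeric starting coordinates.
#' @param penaltySchedule ascending positive penalty weights
#'   (default \code{10^(0:6)}).
#' @param tolerance gap convergence threshold in Hartree (default 1e-6).
#' @param states pair of adjacent states defining the gap (default c(1, 2)).
#' @param maxit Nelder-Mead iterations per stage (default 500).
#' @return list with \code{point}, \code{energies}, \code{gap},
#'   \code{converged} (logical; FALSE reports the best point found after
#'   schedule exhaustion).
#' @export
locateMECI <- function(object, start, penaltySchedule = 10^(0:6),
                       tolerance = 1e-6, states = c(1L, 2L), maxit = 500L) {
  nS <- nStates(object)
  if (any(states < 1L) || any(states > nS) || states[2L] != states[1L] + 1L)
    stopInput("states must be adjacent indices within 1..%d", nS)
  if (is.unsorted(penaltySchedule) || any(penaltySchedule <= 0))
    stopInput("penaltySchedule must be ascending and positive")
  evalPoint <- function(x) {
    E <- predictEnergies(object, x)
    c(lower = E[states[1L]], gap = E[states[2L]] - E[states[1L]])
  }
  x <- as.numeric(start)
  for (sigma in penaltySchedule) {
    obj <- function(p) {
      v <- evalPoint(p)
      v[["lower"]] + sigma * v[["gap"]]^2
    }
    opt <- stats::optim(x, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    x <- opt$par
    if (evalPoint(x)[["gap"]] <= tolerance) break
  }
  v <- evalPoint(x)
  E <- predictEnergies(object, x)
  list(point = x, energies = as.numeric(E), gap = unname(v[["gap"]]),
       converged = unname(v[["gap"]]) <= tolerance)
}
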