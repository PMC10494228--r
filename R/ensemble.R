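## The two model families compared throughout: "omega_cp" learns the smooth
## set {omega, c_0..c_{n-2}} and reconstructs energies through the companion
## matrix; "direct" learns the sorted adiabatic energies themselves and
## serves as the baseline that fails to reproduce intersections.

#' Fit one kernel model per learned scalar field
#'
#' In \code{"omega_cp"} mode every sample is converted with
#' \code{\link{energiesToCP}} and one model is fitted for \eqn{\omega} and
#' for each coefficient \eqn{c_0..c_{n-2}} (n models in total — the same
#' count as the number of states). In \code{"direct"} mode one model per
#' sorted adiabatic energy level is fitted.
#'
#' @param dataset a nonempty \linkS4class{SampledDataset}.
#' @param descriptor a \linkS4class{DescriptorConfig} (default raw).
#' @param mode \code{"omega_cp"} or \code{"direct"}.
#' @param kernel \code{"rbf"} (default) or \code{"matern12"}.
#' @param hyper hyperparameter policy: \code{NULL} for the median-distance
#'   lengthscale heuristic with regularization 1e-10; a list with elements
#'   \code{lengthscale} and \code{regularization} for fixed values; or a
#'   list with \code{lengthscaleGrid}, \code{regularizationGrid} and
#'   optionally \code{folds} (default 5) and \code{seed} (default 1) for
#'   per-field seeded cross-validated grid search.
#' @return a \linkS4class{SurrogateEnsemble}.
#' @export
fitEnsemble <- function(dataset, descriptor = descriptorConfig("raw"),
                        mode = c("omega_cp", "direct"), kernel = "rbf",
                        hyper = NULL) {
  mode <- match.arg(mode)
  if (!is(dataset, "SampledDataset")) stopInput("'dataset' must be a SampledDataset")
  if (nSamples(dataset) < 2L)
    stopInput("at least 2 samples are required, got %d", nSamples(dataset))
  n <- nStates(dataset)
  els <- elements(dataset)
  X <- featurizeMatrix(descriptor, coords(dataset),
                       if (length(els)) els else NULL)
  E <- energies(dataset)

  if (mode == "omega_cp") {
    targets <- matrix(0, nrow(E), n)
    for (i in seq_len(nrow(E))) {
      rec <- energiesToCP(E[i, ])
      targets[i, ] <- c(omega(rec), cpCoeffs(rec))
    }
    labels <- c("omega", paste0("c", 0:(n - 2L)))
  } else {
    targets <- E
    labels <- paste0("E", seq_len(n))
  }

  fitOne <- function(y, label) {
    if (is.null(hyper)) {
      fitKRR(X, y, kernel, medianHeuristic(X), 1e-10, label)
    } else if (!is.null(hyper$lengthscaleGrid)) {
      sel <- selectHyperparams(X, y, hyper$lengthscaleGrid,
                               hyper$regularizationGrid,
                               folds = hyper$folds %||% 5L,
                               seed = hyper$seed %||% 1L, kernel = kernel)
      fitKRR(X, y, kernel, sel$lengthscale, sel$regularization, label)
    } else {
      fitKRR(X, y, kernel, hyper$lengthscale,
             hyper$regularization %||% 1e-10, label)
    }
  }
  models <- lapply(seq_len(n), function(j) fitOne(targets[, j], labels[j]))
  names(models) <- labels
  new("SurrogateEnsemble", mode = mode, nStates = as.integer(n),
      descriptor = descriptor, kernel = kernel, models = models,
      elements = els)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn predictEnergies surrogate prediction; in \code{"omega_cp"}
#'   mode assembles the predicted coefficients into a companion matrix per
#'   point and flags (attribute \code{"unrealizable"}) any point whose
#'   regressed coefficients are not realizable by a real spectrum, returning
#'   eigenvalue real parts there.
setMethod("predictEnergies", "SurrogateEnsemble", function(object, coords, ...) {
  single <- !is.matrix(coords)
  if (single) coords <- matrix(coords, nrow = 1L)
  X <- featurizeMatrix(object@descriptor, coords,
                       if (length(object@elements)) object@elements else NULL)
  n <- object@nStates
  preds <- vapply(object@models, predictKRR, numeric(nrow(X)),
                  newFeatures = X)
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L,
                                     dimnames = list(NULL, names(object@models)))
  out <- matrix(0, nrow(X), n)
  flagged <- logical(nrow(X))
  if (identical(object@mode, "omega_cp")) {
    for (i in seq_len(nrow(X))) {
      res <- companionRoots(preds[i, -1L], n)
      flagged[i] <- res$maxRelImag > 1e-8
      out[i, ] <- sort(res$roots) + preds[i, 1L]
    }
  } else {
    for (i in seq_len(nrow(X))) out[i, ] <- sort(preds[i, ])
  }
  colnames(out) <- paste0("E", seq_len(n))
  if (single) {
    res <- out[1L, ]
    attr(res, "unrealizable") <- flagged[1L]
    res
  } else {
    attr(out, "unrealizable") <- flagged
    out
  }
})

#' @describeIn predictEnergies exact evaluation of an analytic model.
setMethod("predictEnergies", "LinearVibronicModel", function(object, coords, ...) {
  if (!is.matrix(coords))
    return(energies(evaluateModel(object, coords)))
  out <- matrix(0, nrow(coords), object@nStates)
  for (i in seq_len(nrow(coords)))
    out[i, ] <- energies(evaluateModel(object, coords[i, ]))
  colnames(out) <- paste0("E", seq_len(object@nStates))
  out
})

#' Learning curve: test MAE per adiabatic state vs training-set size
#'
#' For each requested size, draws a fresh seeded Latin hypercube training
#' set from the model, fits an ensemble, and reports the per-state mean
#' absolute error on a fixed test set, averaged over replicates.
#'
#' @param model the ground-truth \linkS4class{LinearVibronicModel}.
#' @param trainingSizes ascending integer vector of training-set sizes.
#' @param testSet a \linkS4class{SampledDataset} used for evaluation.
#' @param mode,kernel,descriptor,hyper passed to \code{\link{fitEnsemble}}.
#' @param bounds sampling bounds for the training draws.
#' @param replicates number of independent training draws per size.
#' @param seed base seed; each (size, replicate) derives its own sub-seed.
#' @return a data.frame with columns \code{size}, \code{state}, \code{mae}
#'   (averaged over replicates).
#' @export
maeCurve <- function(model, trainingSizes, testSet,
                     mode = c("omega_cp", "direct"), kernel = "rbf",
                     descriptor = descriptorConfig("raw"), hyper = NULL,
                     bounds = c(-0.25, 0.25), replicates = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.unsorted(trainingSizes))
    stopInput("trainingSizes must be ascending")
  if (nSamples(testSet) < 1L) stopInput("test set is empty")
  testX <- coords(testSet)
  testE <- energies(testSet)
  n <- nStates(testSet)
  rows <- list()
  for (si in seq_along(trainingSizes)) {
    maeAcc <- matrix(0, replicates, n)
    for (r in seq_len(replicates)) {
      subSeed <- (as.integer(seed) + 7919L * si + 104729L * r) %% 2147483647L
      ds <- simulateDataset(model, trainingSizes[si], bounds, subSeed)
      ens <- fitEnsemble(ds, descriptor, mode, kernel, hyper)
      pred <- predictEnergies(ens, testX)
      maeAcc[r, ] <- colMeans(abs(pred - testE))
    }
    rows[[si]] <- data.frame(size = trainingSizes[si], state = seq_len(n),
                             mae = colMeans(maeAcc))
  }
  do.call(rbind, rows)
}
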