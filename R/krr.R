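## Kernel ridge regression of the smooth scalar fields. The RBF kernel is
## the default (the fields omega and c_i are C-infinity); the Matern-1/2
## kernel is provided as the C^0 baseline alternative for direct-energy
## fits.

#' Kernel Gram matrix
#'
#' RBF entries are \eqn{\exp(-\|a - b\|^2 / (2\ell^2))}; Matern-1/2 entries
#' are \eqn{\exp(-\|a - b\| / \ell)}. With \code{X1 = X2} the result is
#' symmetric positive semidefinite.
#'
#' @param kind \code{"rbf"} or \code{"matern12"}.
#' @param X1,X2 feature matrices (rows are points).
#' @param lengthscale positive kernel lengthscale.
#' @return numeric matrix \code{nrow(X1) x nrow(X2)}.
#' @export
kernelMatrix <- function(kind = c("rbf", "matern12"), X1, X2 = X1,
                         lengthscale) {
  kind <- match.arg(kind)
  if (!is.numeric(lengthscale) || length(lengthscale) != 1L ||
      !is.finite(lengthscale) || lengthscale <= 0)
    stopInput("lengthscale must be a single positive number")
  if (!is.matrix(X1)) X1 <- matrix(X1, nrow = 1L)
  if (!is.matrix(X2)) X2 <- matrix(X2, nrow = 1L)
  if (ncol(X1) != ncol(X2))
    stopInput("feature dimension mismatch: %d vs %d", ncol(X1), ncol(X2))
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  if (kind == "rbf") exp(-d2 / (2 * lengthscale^2))
  else exp(-sqrt(d2) / lengthscale)
}

#' Fit a kernel ridge regression model
#'
#' Solves \eqn{(K + \lambda I)\alpha = y} by Cholesky factorization. With
#' regularization at (or near) zero the model interpolates the training
#' targets.
#'
#' @param features numeric matrix of training features (rows are points).
#' @param targets numeric vector of training targets.
#' @param kernel \code{"rbf"} or \code{"matern12"}.
#' @param lengthscale positive kernel lengthscale.
#' @param regularization ridge term (>= 0).
#' @param label optional field label stored with the model.
#' @return a \linkS4class{KernelModel}.
#' @export
fitKRR <- function(features, targets, kernel = "rbf", lengthscale,
                   regularization = 1e-10, label = "field") {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != length(targets))
    stopInput("features has %d rows but targets has length %d",
              nrow(features), length(targets))
  if (nrow(features) < 2L)
    stopInput("at least 2 training points are required")
  if (anyNA(targets) || any(!is.finite(targets)))
    stopInput("targets must be finite")
  if (regularization < 0) stopInput("regularization must be >= 0")
  K <- kernelMatrix(kernel, features, features, lengthscale)
  A <- K + diag(regularization, nrow(K))
  R <- tryCatch(chol(A), error = function(e) e)
  if (inherits(R, "error"))
    stopNumerical(paste0("kernel system is singular (duplicate rows or ",
                         "regularization = 0?): increase 'regularization' ",
                         "above 0 [%s]"), conditionMessage(R))
  alpha <- backsolve(R, forwardsolve(t(R), targets))
  new("KernelModel", kernel = kernel, lengthscale = lengthscale,
      regularization = regularization, features = features,
      alpha = as.numeric(alpha), label = label)
}

#' Predict from a fitted kernel model
#'
#' @param model a \linkS4class{KernelModel}.
#' @param newFeatures feature matrix (rows are points) or a single feature
#'   vector.
#' @return numeric vector of predictions.
#' @export
predictKRR <- function(model, newFeatures) {
  if (!is(model, "KernelModel")) stopInput("'model' must be a KernelModel")
  if (!is.matrix(newFeatures))
    newFeatures <- matrix(newFeatures, nrow = 1L)
  if (ncol(newFeatures) != ncol(model@features))
    stopInput("descriptor mismatch: model expects %d features, got %d",
              ncol(model@features), ncol(newFeatures))
  as.numeric(kernelMatrix(model@kernel, newFeatures, model@features,
                          model@lengthscale) %*% model@alpha)
}

#' Seeded k-fold grid search for KRR hyperparameters
#'
#' Minimizes the mean k-fold cross-validation MAE over the Cartesian grid.
#' Ties are broken toward the larger lengthscale, then the larger
#' regularization (the smoother, better-conditioned model).
#'
#' @param features,targets training data.
#' @param lengthscaleGrid,regularizationGrid nonempty numeric grids.
#' @param folds number of folds k >= 2.
#' @param seed seed for the fold assignment.
#' @param kernel kernel kind.
#' @return list with elements \code{lengthscale}, \code{regularization} and
#'   \code{cvMAE} (the grid of fold-mean MAEs, for diagnostics).
#' @export
selectHyperparams <- function(features, targets, lengthscaleGrid,
                              regularizationGrid, folds = 5L, seed = 1L,
                              kernel = "rbf") {
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  if (length(lengthscaleGrid) < 1L || length(regularizationGrid) < 1L)
    stopInput("hyperparameter grids must be nonempty")
  folds <- as.integer(folds)
  if (folds < 2L) stopInput("at least 2 folds are required")
  if (n < folds)
    stopInput("fewer samples (%d) than folds (%d)", n, folds)
  fold <- withSeed(seed, sample(rep(seq_len(folds), length.out = n)))
  grid <- expand.grid(lengthscale = sort(lengthscaleGrid),
                      regularization = sort(regularizationGrid))
  cv <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    maes <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- tryCatch(
        fitKRR(features[tr, , drop = FALSE], targets[tr], kernel,
               grid$lengthscale[g], grid$regularization[g]),
        error = function(e) NULL)
      maes[f] <- if (is.null(m)) Inf else
        mean(abs(predictKRR(m, features[!tr, , drop = FALSE]) - targets[!tr]))
    }
    cv[g] <- mean(maes)
  }
  ## ties toward larger lengthscale then larger regularization: among the
  ## minima take the last in (lengthscale, regularization) sort order
  best <- which(cv <= min(cv) + 0)
  ord <- order(grid$lengthscale[best], grid$regularization[best])
  pick <- best[ord[length(ord)]]
  list(lengthscale = grid$lengthscale[pick],
       regularization = grid$regularization[pick],
       cvMAE = cbind(grid, mae = cv))
}

## Default lengthscale: median nonzero pairwise distance of (a subsample of)
## the training features — the standard kernel heuristic.
medianHeuristic <- function(features, maxPoints = 500L) {
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  idx <- if (n > maxPoints) round(seq(1L, n, length.out = maxPoints)) else seq_len(n)
  X <- features[idx, , drop = FALSE]
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  d <- sqrt(pmax(d2[upper.tri(d2)], 0))
  d <- d[d > 0]
  if (!length(d)) stopInput("all training features are identical")
  stats::median(d)
}
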