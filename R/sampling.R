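## Training-set generation: Latin hypercube designs around a conical
## intersection, plus dataset assembly with optional Gaussian noise.

#' Latin hypercube sample
#'
#' Stratified design: along every coordinate the \code{nSamples} points fall
#' exactly one per equal-width bin, which is how training geometries are
#' drawn around an intersection geometry.
#'
#' @param dim number of coordinates.
#' @param nSamples number of points (>= 1).
#' @param bounds either a length-2 vector \code{c(lo, hi)} applied to every
#'   coordinate, or a 2-row matrix (rows lo, hi) with one column per
#'   coordinate. Default \code{c(-0.25, 0.25)}.
#' @param seed integer seed; identical seeds give identical designs.
#' @return numeric matrix \code{nSamples x dim}.
#' @export
latinHypercube <- function(dim, nSamples, bounds = c(-0.25, 0.25), seed) {
  dim <- as.integer(dim); nSamples <- as.integer(nSamples)
  if (dim < 1L) stopInput("dim must be >= 1")
  if (nSamples < 1L) stopInput("nSamples must be >= 1")
  b <- .expandBounds(bounds, dim)
  withSeed(seed, {
    X <- matrix(0, nSamples, dim)
    for (k in seq_len(dim)) {
      u <- (sample.int(nSamples) - stats::runif(nSamples)) / nSamples
      X[, k] <- b[1L, k] + u * (b[2L, k] - b[1L, k])
    }
    colnames(X) <- paste0("x", seq_len(dim))
    X
  })
}

.expandBounds <- function(bounds, dim) {
  if (is.matrix(bounds)) {
    if (nrow(bounds) != 2L || ncol(bounds) != dim)
      stopInput("bounds matrix must be 2 x %d", dim)
    b <- bounds
  } else if (is.numeric(bounds) && length(bounds) == 2L) {
    b <- matrix(rep(bounds, dim), 2L, dim)
  } else stopInput("bounds must be c(lo, hi) or a 2 x dim matrix")
  if (any(b[2L, ] <= b[1L, ]))
    stopInput("degenerate bounds: upper must exceed lower in every coordinate")
  b
}

#' Evaluate a model on a coordinate matrix
#'
#' Evaluates the analytic potential at every row of \code{coordMatrix}.
#' Optional zero-mean Gaussian noise (per energy, re-sorted afterwards)
#' emulates imperfect training labels; the default is noiseless, matching
#' electronic-structure training data.
#'
#' @param model a \linkS4class{LinearVibronicModel}.
#' @param coordMatrix numeric matrix, one geometry per row (may be empty).
#' @param noiseSd standard deviation of additive energy noise in Hartree
#'   (default 0).
#' @param seed seed for the noise draw (required when \code{noiseSd > 0}).
#' @param provenance optional list merged into the dataset provenance.
#' @return a \linkS4class{SampledDataset}.
#' @export
makeDataset <- function(model, coordMatrix, noiseSd = 0, seed = NULL,
                        provenance = list()) {
  if (!is(model, "LinearVibronicModel"))
    stopInput("'model' must be a LinearVibronicModel")
  if (!is.matrix(coordMatrix))
    coordMatrix <- matrix(coordMatrix, ncol = model@dim)
  if (nrow(coordMatrix) > 0L && ncol(coordMatrix) != model@dim)
    stopInput("coordMatrix must have %d columns, got %d",
              model@dim, ncol(coordMatrix))
  E <- matrix(0, nrow(coordMatrix), model@nStates)
  for (i in seq_len(nrow(coordMatrix)))
    E[i, ] <- energies(evaluateModel(model, coordMatrix[i, ]))
  if (noiseSd > 0) {
    if (is.null(seed)) stopInput("a seed is required when noiseSd > 0")
    E <- withSeed(seed, E + matrix(stats::rnorm(length(E), 0, noiseSd),
                                   nrow(E), ncol(E)))
    E <- t(apply(E, 1L, sort))
    if (nrow(coordMatrix) == 1L) E <- matrix(E, nrow = 1L)
  }
  colnames(E) <- paste0("E", seq_len(model@nStates))
  prov <- utils::modifyList(
    list(generator = "LinearVibronicModel", nStates = model@nStates,
         noiseSd = noiseSd, seed = seed), provenance)
  new("SampledDataset", coords = coordMatrix, energies = E,
      elements = character(), provenance = prov)
}

#' Latin-hypercube dataset around the intersection of a model
#'
#' Convenience wrapper: \code{\link{latinHypercube}} then
#' \code{\link{makeDataset}}, with provenance recording the generator,
#' bounds and seed.
#'
#' @inheritParams latinHypercube
#' @inheritParams makeDataset
#' @return a \linkS4class{SampledDataset}.
#' @export
simulateDataset <- function(model, nSamples, bounds = c(-0.25, 0.25), seed,
                            noiseSd = 0) {
  X <- latinHypercube(model@dim, nSamples, bounds, seed)
  makeDataset(model, X, noiseSd = noiseSd,
              seed = if (noiseSd > 0) seed + 1L else NULL,
              provenance = list(generator = "latinHypercube",
                                bounds = .expandBounds(bounds, model@dim),
                                seed = seed))
}
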