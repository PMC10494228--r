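#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("energies", function(x, ...) standardGeneric("energies"))

#' @rdname accessors
#' @export
setGeneric("nStates", function(x, ...) standardGeneric("nStates"))

#' @rdname accessors
#' @export
setGeneric("omega", function(x, ...) standardGeneric("omega"))

#' @rdname accessors
#' @export
setGeneric("cpCoeffs", function(x, ...) standardGeneric("cpCoeffs"))

#' Evaluate an analytic model potential at one geometry
#'
#' @param model a \linkS4class{LinearVibronicModel}.
#' @param coords numeric coordinate vector of length \code{dim(model)}.
#' @return a \linkS4class{PotentialSample}.
#' @export
setGeneric("evaluateModel", function(model, coords, ...)
  standardGeneric("evaluateModel"))

#' Predict sorted adiabatic energies from a surrogate or analytic model
#'
#' @param object a \linkS4class{SurrogateEnsemble} or
#'   \linkS4class{LinearVibronicModel}.
#' @param coords a coordinate vector, or a matrix with one point per row.
#' @return for a vector input, a sorted numeric vector of energies; for a
#'   matrix input, a matrix with one row per point. Surrogate predictions in
#'   \code{"omega_cp"} mode carry a logical attribute \code{"unrealizable"}
#'   flagging points whose regressed coefficients gave companion-matrix
#'   eigenvalues with non-negligible imaginary parts (real parts are
#'   returned).
#' @export
setGeneric("predictEnergies", function(object, coords, ...)
  standardGeneric("predictEnergies"))

#' Cone topography at a two-state conical intersection
#'
#' @export
setGeneric("coneParameters",
  function(object, ciPoint, step = 1e-3, relativeThreshold = 1e-2,
           reference = NULL, ...)
  standardGeneric("coneParameters"))

## ---- accessor methods -------------------------------------------------

#' Accessors for omegaCP classes
#'
#' @param x an omegaCP object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
setMethod("coords", "PotentialSample", function(x, ...) x@coords)
#' @rdname accessors
setMethod("coords", "SampledDataset", function(x, ...) x@coords)
#' @rdname accessors
setMethod("energies", "PotentialSample", function(x, ...) x@energies)
#' @rdname accessors
setMethod("energies", "SampledDataset", function(x, ...) x@energies)
#' @rdname accessors
setMethod("nStates", "CPRecord", function(x, ...) x@nStates)
#' @rdname accessors
setMethod("nStates", "PotentialSample", function(x, ...) length(x@energies))
#' @rdname accessors
setMethod("nStates", "LinearVibronicModel", function(x, ...) x@nStates)
#' @rdname accessors
setMethod("nStates", "SampledDataset", function(x, ...) ncol(x@energies))
#' @rdname accessors
setMethod("nStates", "SurrogateEnsemble", function(x, ...) x@nStates)
#' @rdname accessors
setMethod("omega", "CPRecord", function(x, ...) x@omega)
#' @rdname accessors
setMethod("cpCoeffs", "CPRecord", function(x, ...) x@coeffs)

#' @rdname accessors
#' @export
nSamples <- function(x) {
  stopifnot(is(x, "SampledDataset"))
  nrow(x@coords)
}

#' @rdname accessors
#' @export
provenance <- function(x) {
  stopifnot(is(x, "SampledDataset"))
  x@provenance
}

#' @rdname accessors
#' @export
elements <- function(x) {
  if (is(x, "SampledDataset") || is(x, "SurrogateEnsemble")) x@elements
  else stopInput("no elements for class '%s'", class(x))
}

#' @rdname accessors
#' @export
ensembleMode <- function(x) {
  stopifnot(is(x, "SurrogateEnsemble"))
  x@mode
}

#' @rdname accessors
#' @export
componentModels <- function(x) {
  stopifnot(is(x, "SurrogateEnsemble"))
  x@models
}

#' @rdname accessors
#' @export
branchingDim <- function(x) {
  stopifnot(is(x, "ConeReport"))
  x@branchingDim
}

#' @rdname accessors
#' @export
branchingVectors <- function(x) {
  stopifnot(is(x, "ConeReport"))
  x@branchingVectors
}

#' @rdname accessors
#' @export
seamVectors <- function(x) {
  stopifnot(is(x, "ConeReport"))
  x@seamVectors
}

#' @rdname accessors
#' @export
coneTopography <- function(x) {
  stopifnot(is(x, "ConeReport"))
  c(g = x@gNorm, h = x@hNorm, s_x = x@sX, s_y = x@sY)
}
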