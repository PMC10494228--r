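#' @import methods
NULL

## Tolerances for structural validity checks; algebraic tolerances live with
## the operations that own them.
.symTol <- 1e-12

#' One geometry with its sorted adiabatic energies
#'
#' A single training/evaluation record: a nuclear geometry (abstract model
#' coordinates, dimensionless, or flattened Cartesians in Angstrom) together
#' with the n adiabatic energies at that geometry, in Hartree, ascending.
#'
#' @slot coords numeric vector of nuclear coordinates.
#' @slot energies numeric vector of n >= 2 adiabatic energies, ascending.
#' @exportClass PotentialSample
setClass("PotentialSample",
  representation(coords = "numeric", energies = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@coords) < 1L)
      msg <- c(msg, "coords must have length >= 1")
    if (length(object@energies) < 2L)
      msg <- c(msg, "at least 2 adiabatic energies are required")
    if (anyNA(object@coords) || any(!is.finite(object@coords)))
      msg <- c(msg, "coords must be finite")
    if (anyNA(object@energies) || any(!is.finite(object@energies)))
      msg <- c(msg, "energies must be finite")
    if (length(object@energies) >= 2L && is.unsorted(object@energies))
      msg <- c(msg, "energies must be sorted ascending")
    if (length(msg)) msg else TRUE
  })

#' Average energy and characteristic-polynomial coefficients
#'
#' The smooth representation of an n-state adiabatic spectrum: the average
#' adiabatic energy omega = mean(E) and the coefficients c_0, ..., c_{n-2} of
#' the characteristic polynomial of the traceless splitting matrix
#' Z = diag(E) - omega I. The coefficient of lambda^{n-1} is identically zero
#' because Z is traceless, and is not stored. c_i carries units of
#' Hartree^(n-i).
#'
#' @slot omega average adiabatic energy (Hartree).
#' @slot coeffs numeric vector (c_0, ..., c_{n-2}).
#' @slot nStates integer number of electronic states n >= 2.
#' @exportClass CPRecord
setClass("CPRecord",
  representation(omega = "numeric", coeffs = "numeric", nStates = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@omega) != 1L || !is.finite(object@omega))
      msg <- c(msg, "omega must be a single finite number")
    if (length(object@nStates) != 1L || object@nStates < 2L)
      msg <- c(msg, "nStates must be a single integer >= 2")
    if (anyNA(object@coeffs) || any(!is.finite(object@coeffs)))
      msg <- c(msg, "coeffs must be finite")
    if (length(object@nStates) == 1L &&
        length(object@coeffs) != object@nStates - 1L)
      msg <- c(msg, sprintf("expected %d coefficients (c_0..c_{n-2}), got %d",
                            object@nStates - 1L, length(object@coeffs)))
    if (length(msg)) msg else TRUE
  })

#' Analytic linear vibronic coupling model
#'
#' An n-state potential matrix linear in the nuclear coordinates:
#' V(x) = (tilt . x) I + sum_k x_k W_k, with each W_k symmetric and traceless.
#' By construction all n states are degenerate at the origin, which is
#' therefore a point of conical intersection; the branching space there is the
#' span of the W_k in the traceless-symmetric matrix space.
#'
#' @slot nStates integer number of electronic states.
#' @slot dim integer number of nuclear coordinates.
#' @slot tilt numeric gradient of the average energy (E_h per coordinate unit).
#' @slot couplings list of dim traceless symmetric n x n matrices.
#' @exportClass LinearVibronicModel
setClass("LinearVibronicModel",
  representation(nStates = "integer", dim = "integer", tilt = "numeric",
                 couplings = "list"),
  validity = function(object) {
    msg <- character()
    n <- object@nStates; d <- object@dim
    if (length(n) != 1L || n < 2L) msg <- c(msg, "nStates must be >= 2")
    if (length(d) != 1L || d < 1L) msg <- c(msg, "dim must be >= 1")
    if (length(object@tilt) != d)
      msg <- c(msg, "tilt must have length dim")
    if (length(object@couplings) != d)
      msg <- c(msg, "couplings must hold one matrix per coordinate")
    for (k in seq_along(object@couplings)) {
      W <- object@couplings[[k]]
      if (!is.matrix(W) || !all(dim(W) == c(n, n))) {
        msg <- c(msg, sprintf("coupling %d is not %d x %d", k, n, n))
        next
      }
      if (max(abs(W - t(W))) > .symTol)
        msg <- c(msg, sprintf("coupling %d is not symmetric", k))
      if (abs(sum(diag(W))) > .symTol * max(1, max(abs(W))))
        msg <- c(msg, sprintf("coupling %d is not traceless", k))
    }
    if (length(msg)) msg else TRUE
  })

#' A sampled set of geometries with adiabatic energies
#'
#' Row i of \code{coords} is a geometry; row i of \code{energies} holds its
#' sorted adiabatic energies. \code{elements} is empty for abstract model
#' coordinates, or one symbol per atom for molecular (flattened-Cartesian)
#' data. \code{provenance} records how the set was generated (generator name,
#' bounds, seed).
#'
#' @slot coords numeric matrix, one geometry per row.
#' @slot energies numeric matrix, ascending within each row.
#' @slot elements character, one element symbol per atom (may be empty).
#' @slot provenance list of generator metadata.
#' @exportClass SampledDataset
setClass("SampledDataset",
  representation(coords = "matrix", energies = "matrix",
                 elements = "character", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@coords) != nrow(object@energies))
      msg <- c(msg, "coords and energies must have the same number of rows")
    if (nrow(object@energies) > 0L && ncol(object@energies) < 2L)
      msg <- c(msg, "at least 2 states are required")
    if (nrow(object@energies) > 0L) {
      srt <- apply(object@energies, 1L, function(e) !is.unsorted(e))
      if (!all(srt))
        msg <- c(msg, sprintf("energies not ascending in row(s) %s",
                              paste(utils::head(which(!srt), 5), collapse = ", ")))
    }
    if (length(object@elements) > 0L &&
        ncol(object@coords) != 3L * length(object@elements))
      msg <- c(msg, "coords must have 3 columns per element symbol")
    if (length(msg)) msg else TRUE
  })

#' Geometry-to-feature mapping configuration
#'
#' \code{mode = "raw"} passes model coordinates through unchanged.
#' \code{mode = "soap"} builds a rotation-, translation- and (under averaging)
#' permutation-invariant power spectrum from a Gaussian-smeared neighbour
#' density expanded in \code{nMax} radial Gaussians and real spherical
#' harmonics up to \code{lMax}, per ordered species pair, reduced either by
#' averaging over atomic centres or by concatenating per-centre blocks.
#'
#' @slot mode "raw" or "soap".
#' @slot rCut radial cutoff (Angstrom).
#' @slot nMax number of radial basis functions.
#' @slot lMax maximum spherical-harmonic degree.
#' @slot sigmaAtom Gaussian smearing width (Angstrom).
#' @slot species ordered element symbols (soap mode).
#' @slot reduction "average" over centres or "concatenate" per centre.
#' @exportClass DescriptorConfig
setClass("DescriptorConfig",
  representation(mode = "character", rCut = "numeric", nMax = "integer",
                 lMax = "integer", sigmaAtom = "numeric",
                 species = "character", reduction = "character"),
  prototype(mode = "raw", rCut = 5, nMax = 6L, lMax = 4L, sigmaAtom = 0.5,
            species = character(), reduction = "average"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("raw", "soap"))
      msg <- c(msg, "mode must be 'raw' or 'soap'")
    if (!object@reduction %in% c("average", "concatenate"))
      msg <- c(msg, "reduction must be 'average' or 'concatenate'")
    if (identical(object@mode, "soap")) {
      if (object@rCut <= 0) msg <- c(msg, "rCut must be > 0")
      if (object@nMax < 1L) msg <- c(msg, "nMax must be >= 1")
      if (object@lMax < 0L) msg <- c(msg, "lMax must be >= 0")
      if (object@sigmaAtom <= 0) msg <- c(msg, "sigmaAtom must be > 0")
      if (length(object@species) == 0L)
        msg <- c(msg, "soap mode requires a nonempty species list")
      if (anyDuplicated(object@species))
        msg <- c(msg, "species must be unique")
    }
    if (length(msg)) msg else TRUE
  })

#' A fitted kernel ridge regression model for one scalar field
#'
#' Dual-form KRR: predictions are k(x, X) . alpha with
#' (K + regularization I) alpha = y.
#'
#' @slot kernel "rbf" or "matern12".
#' @slot lengthscale kernel lengthscale in feature-space distance units.
#' @slot regularization ridge term (dimensionless, >= 0).
#' @slot features training feature matrix (rows are points).
#' @slot alpha dual weights.
#' @slot label which field this model predicts ("omega", "c0", ..., "E1", ...).
#' @exportClass KernelModel
setClass("KernelModel",
  representation(kernel = "character", lengthscale = "numeric",
                 regularization = "numeric", features = "matrix",
                 alpha = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@kernel %in% c("rbf", "matern12"))
      msg <- c(msg, "kernel must be 'rbf' or 'matern12'")
    if (length(object@lengthscale) != 1L || object@lengthscale <= 0)
      msg <- c(msg, "lengthscale must be a single positive number")
    if (length(object@regularization) != 1L || object@regularization < 0)
      msg <- c(msg, "regularization must be >= 0")
    if (nrow(object@features) != length(object@alpha))
      msg <- c(msg, "alpha must have one weight per training row")
    if (length(msg)) msg else TRUE
  })

#' One fitted kernel model per learned scalar field
#'
#' In \code{"omega_cp"} mode the ensemble holds n models: one for the average
#' energy omega and one per characteristic-polynomial coefficient
#' c_0..c_{n-2}; adiabatic energies are reconstructed through the companion
#' matrix. In \code{"direct"} mode it holds n models of the sorted adiabatic
#' energies themselves (the baseline the smooth representation is compared
#' against).
#'
#' @slot mode "omega_cp" or "direct".
#' @slot nStates number of electronic states.
#' @slot descriptor the DescriptorConfig used to featurize geometries.
#' @slot kernel kernel kind shared by the component models.
#' @slot models named list of KernelModel objects.
#' @slot elements element symbols for molecular data (may be empty).
#' @exportClass SurrogateEnsemble
setClass("SurrogateEnsemble",
  representation(mode = "character", nStates = "integer",
                 descriptor = "DescriptorConfig", kernel = "character",
                 models = "list", elements = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("omega_cp", "direct"))
      msg <- c(msg, "mode must be 'omega_cp' or 'direct'")
    n <- object@nStates
    if (length(n) != 1L || n < 2L) msg <- c(msg, "nStates must be >= 2")
    if (length(object@models) != n)
      msg <- c(msg, sprintf("expected %d component models, got %d",
                            n, length(object@models)))
    if (!all(vapply(object@models, is, logical(1), class2 = "KernelModel")))
      msg <- c(msg, "all component models must be KernelModel objects")
    want <- if (identical(object@mode, "omega_cp"))
      c("omega", paste0("c", seq_len(max(n - 1L, 0L)) - 1L))
    else paste0("E", seq_len(n))
    if (length(object@models) == n && !identical(names(object@models), want))
      msg <- c(msg, sprintf("model names must be %s", paste(want, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Branching-space and cone-topography report at a conical intersection
#'
#' Holds the Hessian of the branching coefficient c_{n-2} at the evaluation
#' point, its eigen-decomposition split into branching (above-threshold) and
#' seam (below-threshold) parts, and — for two-state intersections — the cone
#' parameters: pitch norms gNorm >= hNorm (from the two negative branching
#' eigenvalues -2 g^2 and -2 h^2) and tilts sX, sY (projections of the
#' average-energy gradient on the branching unit vectors), all in E_h per
#' coordinate unit.
#'
#' @slot point coordinates of the evaluation point.
#' @slot hessian symmetric Hessian of c_{n-2}.
#' @slot eigenvalues all eigenvalues, descending by magnitude.
#' @slot branchingVectors orthonormal columns spanning the branching space.
#' @slot seamVectors orthonormal columns spanning the seam space.
#' @slot branchingDim number of above-threshold eigenvalues.
#' @slot gNorm,hNorm,sX,sY two-state cone parameters (NA if branchingDim != 2).
#' @slot principalAngles degrees versus a reference subspace (may be empty).
#' @exportClass ConeReport
setClass("ConeReport",
  representation(point = "numeric", hessian = "matrix",
                 eigenvalues = "numeric", branchingVectors = "matrix",
                 seamVectors = "matrix", branchingDim = "integer",
                 gNorm = "numeric", hNorm = "numeric",
                 sX = "numeric", sY = "numeric",
                 principalAngles = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@branchingVectors) != object@branchingDim)
      msg <- c(msg, "branchingVectors must have branchingDim columns")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PotentialSample", function(object) {
  cat(sprintf("PotentialSample: %d coordinates, %d states\n",
              length(object@coords), length(object@energies)))
  cat("  energies (E_h):", paste(signif(object@energies, 6), collapse = " "), "\n")
})

setMethod("show", "CPRecord", function(object) {
  cat(sprintf("CPRecord (n = %d)\n  omega = %.8g E_h\n  coeffs (c_0..c_%d): %s\n",
              object@nStates, object@omega, object@nStates - 2L,
              paste(signif(object@coeffs, 6), collapse = " ")))
})

setMethod("show", "LinearVibronicModel", function(object) {
  cat(sprintf("LinearVibronicModel: %d states, %d coordinates\n",
              object@nStates, object@dim))
  cat("  tilt:", paste(signif(object@tilt, 4), collapse = " "), "\n")
  nz <- sum(vapply(object@couplings, function(W) any(W != 0), logical(1)))
  cat(sprintf("  %d coordinate(s) carry nonzero coupling\n", nz))
})

setMethod("show", "SampledDataset", function(object) {
  cat(sprintf("SampledDataset: %d samples, %d coordinates, %d states\n",
              nrow(object@coords), ncol(object@coords), ncol(object@energies)))
  if (length(object@elements))
    cat("  elements:", paste(object@elements, collapse = " "), "\n")
  if (!is.null(object@provenance$generator))
    cat("  generator:", object@provenance$generator, "\n")
})

setMethod("show", "DescriptorConfig", function(object) {
  if (identical(object@mode, "raw")) {
    cat("DescriptorConfig: raw (identity on model coordinates)\n")
  } else {
    cat(sprintf(paste0("DescriptorConfig: soap (rCut = %g A, nMax = %d,",
                       " lMax = %d, sigma = %g A, %s)\n"),
                object@rCut, object@nMax, object@lMax, object@sigmaAtom,
                object@reduction))
    cat("  species:", paste(object@species, collapse = " "), "\n")
  }
})

setMethod("show", "KernelModel", function(object) {
  cat(sprintf("KernelModel '%s': %s kernel, l = %.4g, reg = %.3g, %d points\n",
              object@label, object@kernel, object@lengthscale,
              object@regularization, nrow(object@features)))
})

setMethod("show", "SurrogateEnsemble", function(object) {
  cat(sprintf("SurrogateEnsemble: mode = %s, %d states, %s kernel\n",
              object@mode, object@nStates, object@kernel))
  cat("  fields:", paste(names(object@models), collapse = ", "), "\n")
  cat(sprintf("  trained on %d points (%s descriptor)\n",
              nrow(object@models[[1]]@features), object@descriptor@mode))
})

setMethod("show", "ConeReport", function(object) {
  cat(sprintf("ConeReport at (%s)\n",
              paste(signif(object@point, 6), collapse = ", ")))
  cat(sprintf("  branching dimension: %d (seam: %d)\n", object@branchingDim,
              ncol(object@seamVectors)))
  cat("  Hessian eigenvalues:",
      paste(signif(object@eigenvalues, 4), collapse = " "), "\n")
  if (!is.na(object@gNorm)) {
    cat(sprintf("  g = %.4g  h = %.4g  s_x = %.4g  s_y = %.4g  (E_h/coord)\n",
                object@gNorm, object@hNorm, object@sX, object@sY))
  }
  if (length(object@principalAngles))
    cat("  principal angles vs reference (deg):",
        paste(signif(object@principalAngles, 4), collapse = " "), "\n")
})
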