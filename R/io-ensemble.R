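## Ensemble serialization: one JSON archive holding format version,
## metadata and the numeric arrays of every component model. Doubles are
## written with 17 significant digits, so save -> load -> predict is bit
## identical on the same platform.

.ensembleFormatVersion <- 1L

#' Save a fitted ensemble to a JSON archive
#'
#' @param ensemble a \linkS4class{SurrogateEnsemble}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveEnsemble <- function(ensemble, path) {
  if (!is(ensemble, "SurrogateEnsemble"))
    stopInput("'ensemble' must be a SurrogateEnsemble")
  validObject(ensemble)
  d <- ensemble@descriptor
  obj <- list(
    formatVersion = .ensembleFormatVersion,
    mode = ensemble@mode,
    nStates = ensemble@nStates,
    kernel = ensemble@kernel,
    elements = as.list(ensemble@elements),
    descriptor = list(mode = d@mode, rCut = d@rCut, nMax = d@nMax,
                      lMax = d@lMax, sigmaAtom = d@sigmaAtom,
                      species = as.list(d@species), reduction = d@reduction),
    models = lapply(ensemble@models, function(m) list(
      label = m@label, kernel = m@kernel, lengthscale = m@lengthscale,
      regularization = m@regularization,
      nFeatures = ncol(m@features),
      features = as.numeric(m@features),   # column-major
      alpha = m@alpha)))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a fitted ensemble from a JSON archive
#'
#' Archives written by a newer format version are refused with guidance;
#' structurally invalid archives raise a validation error.
#'
#' @param path path to an archive written by \code{\link{saveEnsemble}}.
#' @return a \linkS4class{SurrogateEnsemble}.
#' @export
loadEnsemble <- function(path) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stopInput("corrupted archive %s: %s", path,
                              conditionMessage(e)))
  if (is.null(obj$formatVersion))
    stopInput("%s: not an ensemble archive (no formatVersion)", path)
  if (obj$formatVersion > .ensembleFormatVersion)
    stopInput(paste0("%s was written by format version %d; this build reads ",
                     "up to version %d — upgrade the package to load it"),
              path, obj$formatVersion, .ensembleFormatVersion)
  need <- c("mode", "nStates", "kernel", "descriptor", "models")
  miss <- need[!need %in% names(obj)]
  if (length(miss))
    stopInput("%s: invalid archive, missing field(s) %s", path,
              paste(miss, collapse = ", "))
  d <- obj$descriptor
  descriptor <- descriptorConfig(d$mode, d$rCut, d$nMax, d$lMax, d$sigmaAtom,
                                 unlist(d$species) %||% character(),
                                 d$reduction)
  ## read_json simplifies a list of homogeneous model records to a data.frame
  mrec <- obj$models
  asModel <- function(m) {
    feats <- matrix(unlist(m$features), ncol = m$nFeatures)
    new("KernelModel", kernel = m$kernel, lengthscale = m$lengthscale,
        regularization = m$regularization, features = feats,
        alpha = as.numeric(unlist(m$alpha)), label = m$label)
  }
  models <- if (is.data.frame(mrec))
    lapply(seq_len(nrow(mrec)), function(i) asModel(as.list(mrec[i, ])))
  else lapply(mrec, asModel)
  names(models) <- vapply(models, function(m) m@label, character(1))
  ens <- new("SurrogateEnsemble", mode = obj$mode,
             nStates = as.integer(obj$nStates), descriptor = descriptor,
             kernel = obj$kernel, models = models,
             elements = as.character(unlist(obj$elements) %||% character()))
  validObject(ens)
  ens
}
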