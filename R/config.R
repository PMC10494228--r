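## Run configuration: a JSON document validated before any computation.
## Unknown keys are rejected by name so typos fail loudly instead of being
## silently ignored.

.configSchema <- list(
  top = c("mode", "nStates", "model", "descriptor", "kernel", "sampling",
          "analysis", "paths"),
  model = c("type", "gNorm", "hNorm", "sX", "sY", "nStates", "dim",
            "branchingRank", "seed"),
  descriptor = c("mode", "rCut", "nMax", "lMax", "sigmaAtom", "species",
                 "reduction"),
  kernel = c("kind", "lengthscaleGrid", "regularizationGrid", "lengthscale",
             "regularization", "folds", "seed"),
  sampling = c("bounds", "nSamples", "sizes", "seed", "noiseSd"),
  analysis = c("step", "threshold", "point"),
  paths = c("dataset", "ensemble", "output"))

.checkKeys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stopInput("unknown configuration key '%s' in %s (allowed: %s)",
              unknown[1L], where, paste(allowed, collapse = ", "))
}

#' Validate a run-configuration list
#'
#' Checks every block against the known key set and fills defaults. Unknown
#' keys are rejected with a message naming the key.
#'
#' @param config a named list (typically from \code{\link{readRunConfig}}).
#' @return the validated list, with defaults filled in.
#' @export
validateRunConfig <- function(config) {
  if (!is.list(config)) stopInput("configuration must be a list")
  .checkKeys(config, .configSchema$top, "top level")
  for (blk in c("model", "descriptor", "kernel", "sampling", "analysis",
                "paths")) {
    if (!is.null(config[[blk]])) {
      if (!is.list(config[[blk]]))
        stopInput("configuration block '%s' must be an object", blk)
      .checkKeys(config[[blk]], .configSchema[[blk]], sprintf("block '%s'", blk))
    }
  }
  config[["mode"]] <- config[["mode"]] %||% "omega_cp"
  if (!config[["mode"]] %in% c("omega_cp", "direct"))
    stopInput("mode must be 'omega_cp' or 'direct', got '%s'", config[["mode"]])
  config[["kernel"]] <- config[["kernel"]] %||% list()
  config[["kernel"]]$kind <- config[["kernel"]]$kind %||% "rbf"
  if (!config[["kernel"]]$kind %in% c("rbf", "matern12"))
    stopInput("kernel kind must be 'rbf' or 'matern12'")
  config[["sampling"]] <- config[["sampling"]] %||% list()
  config[["sampling"]]$bounds <- unlist(config[["sampling"]]$bounds) %||% c(-0.25, 0.25)
  config[["sampling"]]$nSamples <- config[["sampling"]]$nSamples %||% 500L
  config[["sampling"]]$seed <- config[["sampling"]]$seed %||% 1L
  config[["sampling"]]$noiseSd <- config[["sampling"]]$noiseSd %||% 0
  config[["analysis"]] <- config[["analysis"]] %||% list()
  config[["analysis"]]$step <- config[["analysis"]]$step %||% 1e-3
  config[["analysis"]]$threshold <- config[["analysis"]]$threshold %||% 1e-2
  config
}

#' Read and validate a JSON run configuration
#'
#' @param path path to a JSON configuration file.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopInput("configuration file not found: %s", path)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stopInput("cannot parse %s: %s", path, conditionMessage(e)))
  validateRunConfig(cfg)
}

## Build the analytic model described by a validated config's model block.
modelFromConfig <- function(config) {
  m <- config[["model"]]
  if (is.null(m)) stopInput("configuration has no 'model' block")
  type <- m$type %||% "firstOrderTwoState"
  switch(type,
    firstOrderTwoState = firstOrderTwoState(
      m$gNorm %||% 0.5, m$hNorm %||% 0.5, m$sX %||% 0, m$sY %||% 0),
    randomLinearVibronic = randomLinearVibronic(
      m$nStates %||% 3L, m$dim %||% 7L, m$branchingRank %||% 5L,
      m$seed %||% 1L),
    stopInput("unknown model type '%s'", type))
}

descriptorFromConfig <- function(config) {
  d <- config[["descriptor"]]
  if (is.null(d)) return(descriptorConfig("raw"))
  descriptorConfig(d$mode %||% "raw", d$rCut %||% 5, d$nMax %||% 6L,
                   d$lMax %||% 4L, d$sigmaAtom %||% 0.5,
                   unlist(d$species) %||% character(),
                   d$reduction %||% "average")
}

hyperFromConfig <- function(config) {
  k <- config[["kernel"]]
  if (!is.null(k$lengthscaleGrid))
    list(lengthscaleGrid = unlist(k$lengthscaleGrid),
         regularizationGrid = unlist(k$regularizationGrid) %||% 1e-10,
         folds = k$folds %||% 5L, seed = k$seed %||% 1L)
  else if (!is.null(k$lengthscale))
    list(lengthscale = k$lengthscale,
         regularization = k$regularization %||% 1e-10)
  else NULL
}
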