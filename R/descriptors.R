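## Geometry -> regression features. Abstract model coordinates pass through
## unchanged ("raw"); molecular Cartesian geometries are mapped to a reduced
## power-spectrum descriptor ("soap"): a Gaussian radial basis times real
## spherical harmonics expansion of the neighbour environment of each atomic
## centre, contracted over the harmonic order m so the result is invariant
## under rigid rotations and translations, and (with averaging over centres)
## under permutations of like atoms.

#' Construct a descriptor configuration
#'
#' @param mode \code{"raw"} (identity on model coordinates) or \code{"soap"}
#'   (power spectrum on molecular Cartesians).
#' @param rCut radial cutoff in Angstrom.
#' @param nMax number of radial Gaussians.
#' @param lMax maximum spherical-harmonic degree.
#' @param sigmaAtom Gaussian smearing width in Angstrom.
#' @param species ordered character vector of element symbols.
#' @param reduction \code{"average"} over centres (size-independent,
#'   permutation invariant) or \code{"concatenate"} per-centre blocks.
#' @return a \linkS4class{DescriptorConfig}.
#' @export
descriptorConfig <- function(mode = c("raw", "soap"), rCut = 5, nMax = 6L,
                             lMax = 4L, sigmaAtom = 0.5,
                             species = character(),
                             reduction = c("average", "concatenate")) {
  mode <- match.arg(mode)
  reduction <- match.arg(reduction)
  new("DescriptorConfig", mode = mode, rCut = as.numeric(rCut),
      nMax = as.integer(nMax), lMax = as.integer(lMax),
      sigmaAtom = as.numeric(sigmaAtom), species = as.character(species),
      reduction = reduction)
}

#' Length of the feature vector produced by a configuration
#'
#' Closed-form count: per centre, every unordered species pair contributes
#' radial-pair blocks for each degree l = 0..lMax — \code{nMax (nMax + 1)/2}
#' radial pairs for a same-species pair, \code{nMax^2} for a cross pair.
#' Averaging keeps one such block; concatenation repeats it per atom.
#'
#' @param config a \linkS4class{DescriptorConfig}.
#' @param nAtoms number of atoms (needed for \code{"concatenate"}).
#' @return integer feature length.
#' @export
featureLength <- function(config, nAtoms = NULL) {
  if (identical(config@mode, "raw"))
    stopInput("featureLength is only defined for soap mode")
  S <- length(config@species)
  nM <- config@nMax
  perCentre <- (S * (nM * (nM + 1L)) %/% 2L +
                (S * (S - 1L)) %/% 2L * nM * nM) * (config@lMax + 1L)
  if (identical(config@reduction, "average")) return(as.integer(perCentre))
  if (is.null(nAtoms))
    stopInput("nAtoms is required for reduction = 'concatenate'")
  as.integer(perCentre * nAtoms)
}

## Radial basis: nMax Gaussians of width sigmaAtom, centred evenly on
## [0, rCut], damped by a smooth cosine cutoff.
.radialBasis <- function(config, r) {
  mu <- seq(0, config@rCut, length.out = config@nMax)
  fcut <- 0.5 * (cos(pi * r / config@rCut) + 1)
  exp(-((r - mu)^2) / (2 * config@sigmaAtom^2)) * fcut
}

#' Map a geometry to a feature vector
#'
#' @param config a \linkS4class{DescriptorConfig}.
#' @param coords numeric coordinate vector; in soap mode a flattened
#'   Cartesian geometry (x1, y1, z1, x2, ...) in Angstrom.
#' @param elementLabels character element symbols, one per atom (soap mode
#'   only; ignored in raw mode).
#' @return numeric feature vector.
#' @examples
#' featurize(descriptorConfig("raw"), c(0.3, -0.1))  # identity
#' @export
featurize <- function(config, coords, elementLabels = NULL) {
  if (!is(config, "DescriptorConfig"))
    stopInput("'config' must be a DescriptorConfig")
  validObject(config)
  if (anyNA(coords) || any(!is.finite(coords)))
    stopInput("coords must be finite")
  if (identical(config@mode, "raw")) return(as.numeric(coords))
  if (length(coords) %% 3L != 0L)
    stopInput("soap mode requires 3 coordinates per atom, got length %d",
              length(coords))
  nAtoms <- length(coords) %/% 3L
  if (is.null(elementLabels) || length(elementLabels) != nAtoms)
    stopInput("soap mode requires one element label per atom")
  unknown <- setdiff(unique(elementLabels), config@species)
  if (length(unknown))
    stopInput("unknown element(s): %s", paste(unknown, collapse = ", "))
  pos <- matrix(coords, ncol = 3L, byrow = TRUE)

  S <- length(config@species)
  nM <- config@nMax; lM <- config@lMax
  nYlm <- (lM + 1L)^2
  perCentre <- featureLength(
    descriptorConfig("soap", config@rCut, nM, lM, config@sigmaAtom,
                     config@species, "average"))

  centreBlock <- function(a) {
    ## expansion coefficients c[s, n, (l,m)] of the neighbour density
    cf <- array(0, dim = c(S, nM, nYlm))
    for (b in seq_len(nAtoms)) {
      if (b == a) next
      dv <- pos[b, ] - pos[a, ]
      r <- sqrt(sum(dv * dv))
      if (r < 1e-12 || r > config@rCut) next
      s <- match(elementLabels[b], config@species)
      g <- .radialBasis(config, r)
      y <- realSphericalHarmonics(lM, dv)
      cf[s, , ] <- cf[s, , ] + outer(g, y)
    }
    ## contract over m per (species pair, radial pair, l)
    out <- numeric(perCentre)
    k <- 0L
    for (s1 in seq_len(S)) for (s2 in s1:S) {
      for (n1 in seq_len(nM)) {
        n2range <- if (s1 == s2) n1:nM else seq_len(nM)
        for (n2 in n2range) {
          for (l in 0:lM) {
            mIdx <- (l * l + 1L):((l + 1L)^2)
            k <- k + 1L
            out[k] <- sum(cf[s1, n1, mIdx] * cf[s2, n2, mIdx])
          }
        }
      }
    }
    out
  }

  blocks <- vapply(seq_len(nAtoms), centreBlock, numeric(perCentre))
  if (identical(config@reduction, "average")) rowMeans(blocks)
  else as.numeric(blocks)
}

## Featurize every row of a coordinate matrix.
featurizeMatrix <- function(config, coordMatrix, elementLabels = NULL) {
  if (!is.matrix(coordMatrix)) coordMatrix <- matrix(coordMatrix, nrow = 1L)
  t(apply(coordMatrix, 1L, featurize, config = config,
          elementLabels = elementLabels))
}

## Featurize one query point consistently with an ensemble's training setup.
.featurizePoint <- function(ensemble, coords) {
  matrix(featurize(ensemble@descriptor, coords,
                   if (length(ensemble@elements)) ensemble@elements else NULL),
         nrow = 1L)
}
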