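## Real spherical harmonics on unit vectors, needed by the power-spectrum
## descriptor. Standard normalization: integral of Y_lm^2 over the sphere
## is 1, so sum_m Y_lm(u) Y_lm(v) = (2l+1)/(4 pi) P_l(u . v) (addition
## theorem), which is what makes the power spectrum rotationally invariant.

## Associated Legendre P_l^m(x) for all 0 <= m <= l <= lMax at one x,
## returned as a list indexed [l + 1][m + 1]. Condon-Shortley phase included.
.assocLegendre <- function(lMax, x) {
  P <- matrix(0, lMax + 1L, lMax + 1L)  # rows l, cols m
  P[1L, 1L] <- 1
  if (lMax >= 1L) {
    somx2 <- sqrt(pmax(0, 1 - x * x))
    ## diagonal: P_m^m = (-1)^m (2m-1)!! (1-x^2)^{m/2}
    for (m in 1:lMax)
      P[m + 1L, m + 1L] <- -P[m, m] * (2 * m - 1) * somx2
    ## first off-diagonal: P_{m+1}^m = x (2m+1) P_m^m
    for (m in 0:(lMax - 1L))
      P[m + 2L, m + 1L] <- x * (2 * m + 1) * P[m + 1L, m + 1L]
    ## upward recurrence in l
    if (lMax >= 2L) for (m in 0:(lMax - 2L)) for (l in (m + 2L):lMax)
      P[l + 1L, m + 1L] <- (x * (2 * l - 1) * P[l, m + 1L] -
                            (l + m - 1) * P[l - 1L, m + 1L]) / (l - m)
  }
  P
}

## Real spherical harmonics Y_lm for one unit vector u, flattened over
## (l, m) with l = 0..lMax, m = -l..l; length (lMax + 1)^2.
realSphericalHarmonics <- function(lMax, u) {
  r <- sqrt(sum(u * u))
  if (r < 1e-300) stopInput("zero direction vector")
  u <- u / r
  ct <- max(-1, min(1, u[3L]))
  phi <- atan2(u[2L], u[1L])
  P <- .assocLegendre(lMax, ct)
  out <- numeric((lMax + 1L)^2)
  idx <- 0L
  for (l in 0:lMax) {
    for (m in (-l):l) {
      idx <- idx + 1L
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      out[idx] <- if (m == 0) N * P[l + 1L, 1L]
        else if (m > 0) sqrt(2) * N * P[l + 1L, am + 1L] * cos(am * phi)
        else sqrt(2) * N * P[l + 1L, am + 1L] * sin(am * phi)
    }
  }
  out
}
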