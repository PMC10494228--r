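# Shared fixtures: every dataset is generated in code at test time.

# Haar-ish random orthogonal matrix via QR with positive-diagonal fix.
randomOrthogonal <- function(n) {
  qr0 <- qr(matrix(rnorm(n * n), n, n))
  Q <- qr.Q(qr0)
  Q %*% diag(sign(diag(qr.R(qr0))), n)
}

randomSortedEnergies <- function(n, lo = -10, hi = 10) {
  sort(runif(n, lo, hi))
}

# The two-state branching-plane model with the reference parameters
# (g = h = 0.5, s_x = 0.25, s_y = 0.1).
referenceTwoState <- function() firstOrderTwoState(0.5, 0.5, 0.25, 0.1)

# Asymmetric, tilted two-state model (ethylene-like parameters).
ethyleneLikeTwoState <- function() {
  firstOrderTwoState(0.213, 0.125, -0.130, -0.046)
}

# A small rigid molecule for descriptor tests: distorted water-like
# arrangement, flattened Cartesians in Angstrom.
waterGeometry <- function() {
  list(coords = c(0, 0, 0.12,
                  0, 0.76, -0.48,
                  0, -0.76, -0.47),
       elements = c("O", "H", "H"))
}

rotateGeometry <- function(coords, R, shift = c(0, 0, 0)) {
  pos <- matrix(coords, ncol = 3, byrow = TRUE)
  as.numeric(t(pos %*% t(R) + matrix(shift, nrow(pos), 3, byrow = TRUE)))
}

rotationMatrix3 <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
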