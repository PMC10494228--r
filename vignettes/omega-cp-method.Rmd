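---
title: "Learning conical intersection seams through characteristic polynomial coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning conical intersection seams through characteristic polynomial coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegaCP)
```

## The model and its assumptions

Adiabatic potential energy surfaces that intersect conically are not
differentiable on the seam, so a smooth regressor fitted to the energies
themselves must fail there: it produces an avoided crossing and misrepresents
both the dimensionality and the geometry of the branching space. This package
fits smooth, electronic-basis-invariant functions instead. Writing the
n-state potential matrix as $V(R) = \omega(R) I + Z(R)$ with
$\omega = \operatorname{tr}V/n$ and $Z$ the traceless diagonal splitting
matrix, the learned quantities are $\omega$ and the characteristic-polynomial
coefficients $c_0,\dots,c_{n-2}$ of $Z$ ($c_{n-1}$ vanishes identically).
Both $\omega$ and the $c_i$ are smooth in the nuclear coordinates across the
seam, are invariant under any orthogonal change of electronic basis (they
depend only on the spectrum), and number exactly $n$ — no redundancy relative
to the energies they encode. Energies are recovered as eigenvalues of the
companion matrix of $\lambda^n + 0\cdot\lambda^{n-1} +
c_{n-2}\lambda^{n-2} + \dots + c_0$, shifted by $\omega$.

The working assumptions are: real symmetric electronic Hamiltonians (no
spin–orbit or complex couplings); adiabatic energies available sorted
ascending, with no diabatic labels (basis invariance makes labels
meaningless); units fixed to Hartree for energies and Å (or dimensionless
model coordinates) for geometries.

The branching-space analysis rests on the identity
$c_{n-2} = -\tfrac{1}{2n}\sum_{i<j}(E_i-E_j)^2$: each squared gap grows
quadratically along branching directions and quartically along seam
directions, so the Hessian of $c_{n-2}$ at an intersection point has the
branching space as column space and the seam space as null space, whatever
the number of intersecting states. For a two-state intersection the two
negative eigenvalues are $-2\tilde g^2$ and $-2\tilde h^2$, and the tilts
are the projections of $\nabla\omega$ on the branching unit vectors.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| kernel | `fitEnsemble` | RBF | the learned fields are $C^\infty$; Matérn-1/2 is kept as the $C^0$ baseline for direct fits |
| lengthscale | `fitKRR` | median pairwise feature distance | standard kernel heuristic; robust across the sampled boxes used here |
| regularization | `fitKRR` | $10^{-10}$ | training labels are noiseless model evaluations; the ridge only stabilizes the factorization |
| sampling bounds | `simulateDataset` | $[-0.25, 0.25]$ per coordinate | matches the plotted extent of branching-plane scans around an intersection; user-settable, since real sampling ranges are system-specific |
| finite-difference step | `coneParameters` | $10^{-3}$ coordinate units | balances $O(h^2)$ truncation against regression-surface noise |
| branching threshold | `splitBranchingSeam` | $10^{-2}$ relative | surrogate Hessians are never exactly zero along the seam |
| degeneracy tolerance | `splitBranchingSeam` | $10^{-3}$ relative | see "Numerical choices" |

Hyperparameters can also be selected per field by seeded k-fold grid search
(`selectHyperparams`; k = 5 default, ties toward the smoother model). The
selection policy is independent per field: nothing in the method couples the
lengthscales of $\omega$ and the $c_i$.

## What the synthetic generator emulates — and what it does not

Training data are drawn from linear vibronic coupling models: potential
matrices linear in the coordinates, $V(x) = (s\cdot x)I + \sum_k x_k W_k$,
with symmetric traceless couplings $W_k$. This is the exact first-order
normal form of a conical intersection, and the two-state member
(`firstOrderTwoState`) is the standard branching-plane cone with parameters
$(\tilde g, \tilde h, s_x, s_y)$. The reference configuration used throughout
tests is $\tilde g = \tilde h = 0.5$, $s_x = 0.25$, $s_y = 0.1$; an
asymmetric tilted variant uses $(0.213, 0.125, -0.130, -0.046)$, values of
ethylene-like magnitude in $E_h$/Å. Geometries are Latin hypercube samples
in a box about the intersection, default half-width 0.25, noiseless labels
(matching electronic-structure training data; optional seeded Gaussian label
noise is available for regularization studies).

What this does **not** emulate: real molecular data have curved seams,
higher-order couplings, and energies from correlated electronic-structure
methods with their own convergence noise; the $c_{n-2}$ field of a linear
model is *exactly* quadratic, so surrogate errors here are purely regression
and conditioning effects. A green test therefore establishes that the
algebra, the reconstruction path, and the branching analysis are correct and
that the smooth representation beats direct energy fits under ideal sampling
— not that any particular molecule's seam is fit to a given accuracy.

## Numerical choices

* **CP coefficients by convolution.** $\det(\lambda I - Z) = \prod_i
  (\lambda - z_i)$ is expanded by iterative polynomial multiplication —
  exact for integer inputs, free of the cancellation pitfalls of
  Newton-identity routes at small $n$. The explicit closed form of the
  coefficients is never needed: for a diagonal $Z$ the product expansion is
  the definition. The internally computed $c_{n-1}$ must vanish to $10^{-12}$
  relative; violation is a hard error.
* **Companion matrix, not a polynomial root finder.** Reconstruction goes
  through the eigenvalues of the companion matrix. Coefficients produced by
  regression can leave the manifold realizable by real spectra; prediction
  then returns eigenvalue real parts and flags the point
  (attribute `"unrealizable"`) rather than failing, keeping pipelines robust.
  `cpToEnergies` on a user-supplied record does fail, with a
  numerical-consistency error, when $|\mathrm{Im}\,\lambda| >
  10^{-8}\max(1, |\mathrm{Re}\,\lambda|)$.
* **Degenerate branching eigenvalues.** For a symmetric cone
  ($\tilde g = \tilde h$) the two branching eigenvectors are defined only up
  to rotation, and for a *fitted* Hessian the eigenvalue gap collapses below
  the regression error, making raw eigenvectors arbitrary. Eigenvalues within
  $10^{-3}$ (relative) of each other are therefore clustered and the cluster
  basis canonicalized by Gram–Schmidt on the projections of the coordinate
  axes onto the cluster subspace. This reproduces the generating model's
  axes in the synthetic setting and reduces to a harmless convention
  elsewhere; subspace-level comparisons should use `principalAngles`, which
  is immune to the convention.
* **Eigenvector sign.** The component of largest magnitude is made positive
  (first index on ties). A first-nonzero-component convention is unstable for
  fitted Hessians, where the leading components are regression residuals of
  arbitrary sign.
* **Tilt extraction.** $s_x, s_y$ are the unscaled projections of the
  central-difference $\nabla\omega$ onto the branching unit vectors; this
  reproduces the reference model's parameters exactly and carries
  $E_h$/coordinate units directly. $x$ is the steeper direction
  ($\tilde g \ge \tilde h$), making reports deterministic.
* **Degenerate inputs.** Full $n$-fold degeneracy gives exactly zero
  coefficients; partial degeneracy a repeated polynomial root. A zero Hessian
  yields branching dimension 0 — a valid "no intersection curvature" result,
  while `coneParameters` refuses (unsupported topology) any branching
  dimension other than 2, since the cone parameters are two-state constructs.
* **Interpolation conditioning.** With regularization $\to 0$ the kernel
  system is near-singular; smooth targets still interpolate to $\sim 10^{-7}$,
  but the nonsmooth direct-mode targets lose several digits at wide
  lengthscales. This is a property of the baseline being emulated, not a
  defect of the smooth representation.

## Design decisions taken where the design was open

* **Descriptor.** For molecular Cartesians a reduced in-house power spectrum
  is used (Gaussian radial basis × real spherical harmonics, contracted over
  the harmonic order per species pair, cosine cutoff): rotation-, then
  translation- and, after averaging over centres, permutation-invariant. No
  R-native implementation of the full smeared-density descriptor exists in
  the supported environment; the reduced form satisfies the same invariances
  and length contract and is plumbing, not the contribution. Its parameters
  are selected by plain grid search, not genetic optimization, which adds no
  methodological content.
* **Sampling bounds** are a required user choice with default
  $[-0.25, 0.25]$: published applications do not state their hypercube
  ranges, and sensible ranges are system-specific.
* **Per-field hyperparameters.** Whether baseline comparisons share
  hyperparameters across states is unstated in the literature this follows;
  independent per-field selection is used, which favours the baseline if
  anything.
* **Serialization** uses a single JSON archive with 17-significant-digit
  numbers: bit-exact round trips without binary formats.
* **Branching-rank generator.** `randomLinearVibronic` assigns independent
  traceless-symmetric basis matrices (off-diagonal generators first, then
  adjacent diagonal differences) with coefficients uniform in $[0.1, 1]$ to
  the first `branchingRank` coordinates and zero coupling to the rest, so the
  requested rank is exact by construction and the remaining coordinates are
  pure seam directions.

## Known limitations

* Cone topography parameters are two-state constructs; three-state
  intersections get a correct branching/seam split (dimension 5) but no
  $\tilde g/\tilde h/s$ report.
* Nonadiabatic coupling *vectors* are out of scope: the representation is
  deliberately built from energies alone.
* With coupling-strength ratios beyond ~10 the smallest branching eigenvalue
  approaches the default 1 % relative threshold; analyses of such models
  should lower `relativeThreshold` (the noiseless analytic tests use
  $10^{-3}$).
* Descriptor gradients are not implemented; intersection searches use
  derivative-free optimization (`locateMECI`, penalty method with an
  increasing weight schedule).

## A complete small run

```{r example, eval = FALSE}
model <- firstOrderTwoState(0.5, 0.5, sX = 0.25, sY = 0.1)
train <- simulateDataset(model, 1000, c(-0.25, 0.25), seed = 42)
surrogate <- fitEnsemble(train, mode = "omega_cp")
coneParameters(surrogate, c(0, 0))
locateMECI(surrogate, start = c(0.1, 0.1))
```

Every number shown in the package documentation is produced by running this
code; the test suite regenerates all datasets programmatically under fixed
seeds.
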