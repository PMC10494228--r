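# omegaCP

Machine learning of adiabatic potential energy surfaces (PESs) near seams of
conical intersection, for photochemists and method developers who need
surrogate excited-state potentials that keep the intersection topology intact.

## The problem and the method

At a conical intersection (CI) two or more adiabatic PESs are degenerate and
split linearly along the *branching space*; the adiabatic energies are only
C⁰ there, so fitting them directly with smooth regressors (kernels, neural
networks) rounds the intersection into an avoided crossing and corrupts the
branching-space dimensionality and topography.

omegaCP instead learns smooth functions of geometry. Decompose the n-state
potential matrix as

    V(R) = ω(R) I + Z(R),      ω = tr V / n,   Z = diag(E_i − ω)

and take the characteristic polynomial of the traceless splitting matrix,

    det(λI − Z) = λⁿ + c_{n−1} λ^{n−1} + ⋯ + c_0,     c_{n−1} ≡ 0.

The set {ω, c_0, …, c_{n−2}} — n quantities, the same count as the energies —
is smooth across the seam and invariant to the choice of electronic basis.
Energies are recovered as eigenvalues of the companion matrix of the learned
polynomial, shifted by ω. Because

    c_{n−2} = −(1/2n) Σ_{i<j} (E_i − E_j)²,

the Hessian of this single coefficient at a CI point has the branching space
as its column space and the seam space as its null space. For a two-state CI
its two negative eigenvalues are −2g̃² and −2h̃² (the orthogonalized
gradient-difference and derivative-coupling norms), and the tilt parameters
are s_x = ∇ω·x̂, s_y = ∇ω·ŷ along the branching directions.

The package provides:

* exact algebra between energies and (ω, CP coefficients) (`energiesToCP`,
  `cpToEnergies`, `gapSumIdentity`, `cpInvarianceCheck`);
* analytic linear vibronic coupling models and Latin hypercube samplers as
  ground truth (`firstOrderTwoState`, `randomLinearVibronic`,
  `simulateDataset`);
* kernel ridge regression (RBF / Matérn-1/2) of either the smooth fields
  ("omega_cp" mode) or the raw energies ("direct" mode, the baseline)
  (`fitEnsemble`, `predictEnergies`, `maeCurve`);
* a rotation/translation/permutation-invariant power-spectrum descriptor for
  molecular Cartesian geometries (`descriptorConfig`, `featurize`);
* branching/seam analysis and cone topography (`hessianCnm2`,
  `splitBranchingSeam`, `coneParameters`, `principalAngles`, `gapScan`,
  `locateMECI`);
* dataset (CSV / extended XYZ) and model I/O plus a CLI (`exec/omegacp`)
  with `simulate`, `fit`, `predict`, `learning-curve`, `analyze`.

## Worked example

Fit a surrogate to the standard two-state branching-plane model with
g̃ = h̃ = 0.5, s_x = 0.25, s_y = 0.1 (E_h per coordinate unit) and recover
the cone topography from the fitted fields:

```r
library(omegaCP)
model <- firstOrderTwoState(0.5, 0.5, sX = 0.25, sY = 0.1)
train <- simulateDataset(model, 1000, c(-0.25, 0.25), seed = 42)
surrogate <- fitEnsemble(train, mode = "omega_cp")
coneParameters(surrogate, c(0, 0))
#> ConeReport at (0, 0)
#>   branching dimension: 2 (seam: 0)
#>   Hessian eigenvalues: -0.5 -0.5
#>   g = 0.5  h = 0.5  s_x = 0.25  s_y = 0.1  (E_h/coord)
```

The two Hessian eigenvalues −0.5 = −2·(0.5)² confirm the branching-plane
curvature, and all four cone parameters match the generating model. The
surrogate reproduces the degeneracy itself (gap ≈ 2·10⁻⁴ E_h at the CI),
while a direct fit of the energies on the same data does not:

```r
direct <- fitEnsemble(train, mode = "direct")
line <- cbind(seq(-0.2, 0.2, length.out = 81), 0)
gapScan(direct, line)$minGap      # 0.024  — avoided crossing
gapScan(surrogate, line)$minGap   # 0.00018 — true intersection
```

## Acceptance script

`scripts/acceptance.R` re-runs the headline pipeline from scratch — samples
2000 Latin-hypercube geometries around the reference two-state CI, fits the
smooth-representation surrogate, and recomputes the branching dimension and
the cone parameters from the fitted fields — then writes the target report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
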