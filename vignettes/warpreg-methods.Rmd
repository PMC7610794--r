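---
title: "Registration with a symmetric singular-value prior: models and methods"
author: "warpreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration with a symmetric singular-value prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

warpreg estimates a small-deformation nonlinear transformation
$t(x) = x + d(x)$ mapping the coordinate frame of a reference volume $f$
onto a moving volume $g$, so that $g(t(x)) \approx f(x)$. Each component of
the displacement $d$ (in mm) is a uniformly spaced 3D cubic B-spline
expansion; the parameters are the $3M$ spline coefficients $w$ (the x-, y-
and z-warps). The fitted objective is

$$ C(w) \;=\; \tfrac{v}{2}\sum_n r_n^2 \;+\; \lambda\, P(w), \qquad
   r_n = f_n - g(t(x_n)), $$

where the sum runs over the voxel centres $x_n$ of the (possibly
subsampled) reference grid, $v$ is the voxel volume in mm$^3$, and $P$ is
one of three regularisers. Both terms are volume-weighted Riemann sums, so
the trade-off weight $\lambda$ has the same meaning at every pyramid level
regardless of subsampling.

### The SPRED penalty

At each voxel the local Jacobian of the transformation,
$J = I + \partial d / \partial(x,y,z)$ (taken with respect to world mm
coordinates), decomposes as $J = U S V^\top$. The rotations $U, V$ do not
distort the image; the singular values $s_1, s_2, s_3$ are the orthogonal
scaling factors of the local deformation. The default penalty places a
lognormal prior on them:

$$ P(w) = \sum_n v\,(1 + |J_n|) \sum_{i=1}^3 \log^2 s_i . $$

The $\log^2 s_i$ term makes $s_i = 1$ most likely, $s_i \in \{0, \infty\}$
impossible, and $s_i = a$ exactly as costly as $s_i = 1/a$: expansions and
contractions are penalised equally, which is what encourages
inverse-consistent behaviour. The $(1+|J_n|)$ factor symmetrises the
penalty between the two images: it accounts for the volume that the voxel
occupies in *both* frames. Because the penalty diverges as any $s_i \to 0$
(equivalently as $|J| \to 0^+$), it simultaneously acts as a soft
diffeomorphism constraint.

Computing an SVD per voxel per iteration would dominate the run time, so
the registration path never performs one. With

$$ \log^2 x \;\approx\; x + \tfrac1x - 2 \;=\; \frac{(x-1)^2}{x} $$

applied to $x = s_i^2$ (using $\log^2 s = \log^2(s^2)/4$), and
$\operatorname{tr}(J^\top J) = \sum_i s_i^2$,
$\operatorname{tr}(J^{-\top} J^{-1}) = \sum_i s_i^{-2}$, the penalty
becomes an explicit function of the entries of $J$ alone:

$$ P(w) \approx \sum_n \frac{v\,(1+|J_n|)}{4}
   \operatorname{tr}\!\left(J_n^\top J_n + J_n^{-\top} J_n^{-1} - 2I\right). $$

`spred_value_exact()` (explicit SVDs) is retained purely as a testing
oracle for this SVD-free path. The surrogate is exact to second order at
$s = 1$ and over-estimates $\log^2$ away from it; under the lognormal
prior the penalty itself encodes (log singular values $\sim N(0,
(\log 3/3)^2)$, i.e. $3\sigma$ at a three-fold scaling), total exact and
surrogate penalties agree to within about 15%. For singular values pushed
uniformly to the ends of $[1/3, 3]$ the gap grows towards ~45% per voxel
at $s = 3$ — the surrogate is a *prior*, not a numerical approximation
guarantee, and the package's tests sample it as such.

### Comparison penalties

Two alternatives are provided for contrast experiments, assembled with the
identical gradient/Hessian machinery:

* **Jacobian-determinant penalty** $\sum_n v (1+|J_n|) \log^2 |J_n|$
  (same $\log^2$ surrogate applied to $|J|^2$). It penalises only volume
  change: $J = \mathrm{diag}(2, 1/2, 1)$ has $|J| = 1$ and costs nothing
  despite a four-fold anisotropy, so optimisation under it buys data fit
  with gratuitous shape distortion (visible as a higher mean CVAR at a
  narrower determinant range).
* **Local rigidity penalty** $\sum_n v\,\|J_n^\top J_n - I\|_F$. It
  penalises any non-rigidity but stays *finite* as $|J| \to 0$, so it
  cannot by itself maintain invertibility; with the diffeomorphism guard
  disabled it may produce folded warps.

### Gradient and Gauss–Newton Hessian

Writing the penalty as $\sum_n c_n = \tfrac12 \sum_n a_n^2$ gives the
Gauss–Newton form: gradient $\nabla C = \sum_n \partial c_n/\partial w$
and Hessian

$$ H_{jk} = \sum_{n \in V_j \cap V_k} \frac{1}{2 c_n}
   \left(\frac{\partial c_n}{\partial w_j}\right)
   \left(\frac{\partial c_n}{\partial w_k}\right), $$

where $V_m$ is the support set of spline $m$. The per-voxel $1\times 9$
rows $\partial c_n/\partial J$ are closed-form (cofactor matrix for
$\partial|J|/\partial J$, $2J$ for $\partial \operatorname{tr}(J^\top
J)/\partial J$, $-2 J^{-\top} J^{-1} J^{-\top}$ for the inverse term); the
$\partial J/\partial w$ factors are fixed spline spatial-derivative
stencils. The package realises the support-overlap sparsity with sparse
matrix algebra: a sparse $N \times 3M$ matrix $G$ with
$G_{nm} = \partial c_n/\partial w_m$ is assembled from the nine "partial
derivative images" and the Kronecker-product basis matrices, and
$H = G^\top \mathrm{diag}(1/2c_n)\, G$, symmetric positive semidefinite by
construction. Only coefficient pairs within four knot spacings interact.

The $1/(2c_n)$ factor is singular where the density vanishes (any voxel at
the penalty's minimum). Voxels with $c_n < 10^{-12}\, v$ are excluded from
the Hessian; in the extreme case of an identity warp this leaves $H = 0$,
which is the correct Gauss–Newton statement that the quadratic model is
flat at the global minimum (the Levenberg damping below keeps the step
defined).

## Optimisation

Levenberg-damped Gauss–Newton: solve $(H + \lambda_L I)\,\delta =
-\nabla C$, accept the step only if the total cost decreases **and** every
Jacobian determinant at the level's voxel centres stays positive (the
diffeomorphism guard; an infinite penalty from a folded candidate is an
automatic rejection). $\lambda_L$ starts at
$0.05\, \overline{\mathrm{diag}\, H}$, is divided by 5 on acceptance and
multiplied by 10 on rejection; a level terminates with a warning after 12
consecutive rejections or when $\lambda_L$ exceeds $10^{12}$. Convergence
is declared at a relative cost decrease below $10^{-6}$. The starting
damping is deliberately conservative: the first step of a level is taken
where the penalty's Gauss–Newton Hessian has been floored to zero (the
identity warp is the penalty's flat minimum), so an undamped first step is
a pure data-term jump that badly overshoots and then costs many
iterations to walk back; the asymmetric up/down factors avoid the
accept/reject sawtooth a symmetric schedule produces.

The damped system is solved directly (sparse Cholesky) up to 3000
parameters and by Jacobi-preconditioned conjugate gradients (relative
residual $10^{-8}$) above that; direct factorisation of the 3D-structured
Hessian fills in badly at larger sizes while CG converges quickly on the
damped system. A majorise-minimise mode (`optimiser = "mm"`) replaces $H$
by the diagonal matrix of its absolute column sums, which majorises $H$ by
Gershgorin's theorem — the Hessian-free fallback for very large parameter
counts.

### Pyramid

The default desk-scale schedule, in units of the reference voxel size:

| level | smoothing FWHM | subsampling | knot spacing | max iterations |
|-------|----------------|-------------|--------------|----------------|
| 1     | 4 voxels       | 4           | 8 voxels     | 20             |
| 2     | 2 voxels       | 2           | 8 voxels     | 12             |
| 3     | 1 voxel        | 2           | 4 voxels     | 8              |

Both images are smoothed; only the reference sampling grid is subsampled
(the moving image is always interpolated at its native resolution). The
warp is carried between levels by evaluating its displacement on the new
grid and least-squares refitting the new coefficient lattice, which is
exact up to spline-refinement accuracy. Production registrations of real
brain data would continue to finer knots; the schedule here is chosen so
that a full 64³ registration completes in minutes on one CPU, and every
stage is configurable through `registration_config()`.

### The trade-off weight

The weight $\lambda$ is, as for any registration cost of this family,
calibrated empirically. The packaged default $\lambda = 3\times 10^{-5}$
was fixed by a two-step protocol on the package's synthetic fixtures
(intensities of order 1, structured phantoms, SNR 20). First a balance
measurement bounds the useful range: at the *ground-truth* warp of a
desk fixture the penalty evaluates to $\sim 1.7\times 10^5$
(volume-weighted units) while the similarity noise floor is $\sim 1$, so
any $\lambda \gtrsim 10^{-4}$ makes the true deformation more expensive
than not registering at all and the fit is structurally biased towards
identity. A sweep inside the admissible decade then showed a flat optimum
of the recovered-displacement error around $\lambda = 10^{-5}$–$10^{-4}$;
the default sits in its middle. Images on other intensity scales need
$\lambda$ rescaled accordingly (the data term scales with intensity²).
Warp-quality comparisons between *different* penalties are only
meaningful at matched registration accuracy. `calibrate_weight()`
automates one version of that calibration (adjusting $\lambda$ to a
target final MSQ); the packaged contrast checks instead match on mean
label overlap — choosing the largest comparison weight that still reaches
the SPRED fit's Jaccard within a tolerance — because a volume-only
penalty cannot in general reach the intensity-level fit of the
singular-value penalty at any weight at which it is still active, while
overlap, the accuracy measure that matters, saturates earlier.

## Transformation details

* Geometry is world mm throughout: `world = origin + index * voxel_size`,
  0-based indices, axis-aligned grids. Jacobians are with respect to mm,
  so the identity transform yields $J = I$ under any voxel anisotropy.
  Displacement fields are stored in mm (4D NIfTI, 3 components).
* The coefficient lattice extends one knot beyond each face of the
  reference grid (knot $k$ at `origin + (k-2)h`, $K = \lceil
  \mathrm{extent}/h \rceil + 3$ per axis), so every voxel centre has full
  $4^3$ support and no boundary special-casing is needed in the gradient
  sparsity. Boundary coefficients are free parameters.
* Penalties and the guard are evaluated at the voxel centres of the
  current level's grid — no sub-voxel sampling. A warp can in principle
  fold between samples; the penalty's divergence makes this unlikely but
  the check is deliberately the same set of points the cost uses.
* Image interpolation for the similarity term is interpolating cubic
  B-spline (recursive prefilter, mirror boundaries), so the moving-image
  gradient used by Gauss–Newton is the analytic derivative of a $C^2$
  interpolant — consistent with the smoothness the optimiser assumes, and
  well-behaved under finite-difference verification. Samples outside the
  moving volume take a declared fill value (0, the brain-extracted
  convention) and contribute no residual and no derivative. Labels always
  use nearest-neighbour.
* `invert_warp()` is fixed-point iteration $d^{-1}(x) \leftarrow -d(x +
  d^{-1}(x))$ (default tolerance 0.01 mm, 50 iterations), refused for
  non-diffeomorphic warps, and reports composition residuals. It exists
  for symmetry testing, not as part of the estimation.

## Warp-quality metrics

`jacdet_stats()` reports the histogram and min/max/mean/5th/95th
percentiles of the determinant and its log (percentiles by linear
interpolation of order statistics; log statistics are flagged off when
non-positive determinants are present). The 5th–95th log-determinant range
is the summary measure of volume-distortion aggressiveness.

`cvar_map()` computes the cube-volume aspect ratio
$(s_1^3/(s_1 s_2 s_3))^{1/3} = s_1/|J|^{1/3}$: the cube root of the ratio
between the volume of the smallest cube enclosing the image of a deformed
unit cube and the actual deformed volume. It is 1 for rigid motion and
isotropic scaling and grows with anisotropic shape change; its in-mask
mean is the summary measure of shape distortion. Note CVAR is *not*
symmetric under warp inversion ($\mathrm{diag}(2,1,1)$ gives $4^{1/3}$,
its inverse $2^{1/3}$); singular values here are obtained from the
closed-form symmetric eigensolve of $J^\top J$, not an SVD.

`overlap_scores()` gives per-label Jaccard, Dice, sensitivity and
specificity from the 2×2 contingency of reference versus
nearest-neighbour-transported labels.

## The synthetic fixtures

`make_phantom()` emulates the aspects of brain-extracted structural
images the method interacts with: ellipsoidal structures with flat
interiors and smooth edges (contrast concentrated at boundaries, as in
T1-weighted white matter), a broad background modulation, and a
mid-frequency Gaussian-bump texture so intensity gradients exist
everywhere at the registration scales. It does not simulate MRI physics —
no bias fields, no multi-contrast, no realistic anatomy — so tests passing
on it demonstrate the estimator's correctness and stability, not clinical
performance.

`make_diffeo_warp()` draws lattice-smoothed Gaussian coefficients, scales
them to a requested maximum displacement, and verifies min $|J| > 0.1$
(increasing the lattice smoothing and redrawing when the bound fails, with
an error if the amplitude is not achievable). `make_pair()` wires a
ground-truth pair: the *reference* is the phantom resampled through the
true warp and the *moving* image is the phantom plus noise, so the
returned `true_warp` is exactly the spline warp that registration of
(ref, moving) should recover — the orientation matters, because the other
assignment would make the ground truth the warp's (non-spline) inverse.
`snr` is the standard deviation of the phantom intensities divided by the
noise standard deviation (the image-SD convention; a range-based
definition would put the noise floor at tens of percent of the initial
mismatch and make high MSQ-reduction figures meaningless). Default desk
geometry is 64³ voxels at 2 mm. `make_pair()` also returns an interior
evaluation mask excluding the boundary belt reachable by the warp;
passing it as the similarity mask is recommended practice — voxels whose
warped sample crosses the moving-image boundary switch between data and
fill discontinuously, which damages the smoothness the line-search
assumes (with real brain-extracted data the brain mask plays this role).

## Problem sizes used by the packaged checks

The package's own test material runs at deliberately modest sizes chosen
once: derivative oracles on ~16³ grids with ~5³ knot lattices,
penalty-identity checks on 10⁴ random Jacobians, guard behaviour across
twenty 64³ registrations at a single coarse pyramid level, and one full
default-pyramid recovery at 64³ with four-voxel true displacements at
SNR 20. These sizes exercise every code path (including the CG solver
branch) while keeping the whole suite in the minutes range.

## Known limitations

* Small-deformation model: no velocity-field composition; very large
  deformations are out of scope.
* Affine alignment is assumed; only axis-aligned NIfTI grids are read.
* Similarity is mean-squares only — the intended regime is same-modality,
  intensity-matched pairs (as in the synthetic fixtures).
* The guard and penalties sample voxel centres only (see above).
* Uniform knot spacing per axis; no spatially varying penalty weight.
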