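---
title: "Methods: Steklov-spectrum evaluation of root canal shape"
author: "canalssd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Steklov-spectrum evaluation of root canal shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Root canal preparation mechanically enlarges and cleans the canal cavity
before obturation.  Its quality is traditionally scored from µCT
reconstructions by slice-integrated volume, lateral area and centerline
transportation, but these collapse the whole 3-D shape into a few scalars:
canals with equal volume and very different wall morphology score alike.
`canalssd` instead compares shapes through the spectrum of the
Dirichlet-to-Neumann (Steklov) operator of the cavity surface — an
*extrinsic* shape descriptor that is sensitive to concavity, convexity and
volume, unlike the intrinsic Laplace–Beltrami spectrum — and scores a
prepared canal by its weighted spectral distance (SSD) to an automatically
constructed *ideal* benchmark canal.

## The model

For a bounded solid $\Omega \subset \mathbb{R}^3$ with boundary
$\Sigma$, the Steklov problem seeks harmonic $u$ with
$\partial u/\partial n = \lambda\, u$ on $\Sigma$; the eigenvalues
$0 = \lambda_0 < \lambda_1 \le \lambda_2 \le \dots$ (units mm$^{-1}$) are
the spectrum of the Dirichlet-to-Neumann map.  They are invariant under
rigid motions and scale as $\lambda(s\Omega) = \lambda(\Omega)/s$.

### Boundary-element discretization

The problem is reformulated with layer potentials built on the Laplace
fundamental solution $U^*(x,y) = 1/(4\pi|x-y|)$ and discretized by a
Galerkin method with piecewise-linear hat functions on the triangle mesh:
single layer $V$, double layer $K$ (kernel
$\langle x-y, n_y\rangle/4\pi|x-y|^3$), its adjoint $K^* = K^\top$,
hypersingular $D$, and mass matrix $G$.  The symmetric
Steklov–Poincaré (Schur-complement) form of the eigenproblem is

$$\left[\, D + (G_\sigma + K)^\top V^{-1} (G_\sigma + K) \right] u
   \;=\; \lambda\, G\, u,$$

with $G_\sigma$ the Galerkin realization of the interior solid-angle
coefficient $\sigma(x)$.  On the unit ball the exact spectrum is
$\lambda = k$ with multiplicity $2k+1$; the package reproduces it to
0.8% at icosphere subdivision 2 (162 vertices) and 0.2% at subdivision 3,
which is the oracle the test suite pins.

**$\sigma$ default.** $\sigma(x) = 1/2$ at every smooth boundary point, and
the set where a polyhedral mesh deviates from $1/2$ (its vertices and
edges) has measure zero, so the Galerkin weak form sees only $1/2$.  The
per-vertex polyhedral solid angle converges to $1/2$ merely at $O(h)$
(e.g. $\approx 0.479$ on a subdivision-4 icosphere), and weighting the
mass matrix with it empirically biases the ball eigenvalues several
percent low.  `solve_steklov()` therefore defaults to `sigma = "half"`;
the computed per-vertex fractions are still exposed
(`solid_angle_coefficient()`, `ops$sigma`, `sigma = "vertex"`) for
genuinely creased geometry.

### Quadrature

Far triangle pairs (centroid distance beyond $\eta(r_1+r_2)$, $\eta = 2$)
use a tensor Gauss rule of the requested order (default a 7-point
degree-5 rule per triangle).  Coincident, adjacent and close pairs use
adaptive outer subdivision (depth 3) with **exact closed-form inner panel
integrals**: $\int_T R^{-1}$, $\int_T (y-\rho)R^{-1}$,
$\int_T (y-\rho)R^{-3}$ from edge-based divergence identities, and
$\int_T \langle y-p,n\rangle R^{-3}$ as the van Oosterom–Strackee signed
solid angle.  The weak singularities are thus integrated analytically;
each formula is verified in the tests against a 64-point product-rule
oracle.  The hypersingular $D$ is assembled in the integration-by-parts
(surface-curl) weak form
$d_{ij} = \frac{1}{4\pi}\iint \langle \mathrm{curl}_\Sigma\phi_i(x),
\mathrm{curl}_\Sigma\phi_j(y)\rangle/|x-y|$, which is the standard
regularization of the divergent direct kernel; a structural consequence is
$D\mathbf{1} = 0$ to machine precision, which the tests assert.

Because every quadrature weight is homogeneous in the vertex coordinates,
the discrete eigenvalues obey the continuous scaling and isometry laws
*exactly* (to rounding), independent of quadrature accuracy — the 1e-8
invariance tests check floating-point conservation, not discretization
error.

### Eigen path and ICCG

$V$ is symmetrically diagonal-equilibrated and Cholesky-factored; the
generalized problem is reduced with the Cholesky factor of $G$ and solved
densely.  A shift-invert iterative path for very large meshes was
considered and rejected: every shipped workload stays below ~4k vertices,
where the dense path is both faster and simpler.  The
incomplete-Cholesky preconditioned conjugate-gradient component is
provided as `iccg_solve()` (drop pattern = sparsity of `A`, diagonal-shift
fallback on breakdown) and validated against direct solves; it is kept as
a first-class component because incomplete-Cholesky CG is the classical
inner solver for these SPD systems, even though the dense path does not
need it.

## The ideal benchmark canal

The canal's z-extent is split into coronal/middle/apical segments
(default thirds — the anatomy literature names the thirds but no exact
fractions; configurable).  In each segment three candidate sections are
cut at depths $h_{seg}/3 - a$, $h_{seg}/3$, $h_{seg}/3 + a$ below the
segment top with $a = 0.05\,h_{seg}$, scored by the mean absolute radial
deviation $\bar d$ of boundary points from the equal-area circle radius
$r_{ideal} = \sqrt{A/\pi}$, and the minimizer is kept.  The absolute
deviation (rather than a signed mean, which cancels) and the equal-area
radius are the unique readings under which a circular section scores
exactly zero.  The centroid is the polygon *area*
centroid (robust to nonuniform boundary sampling), not the vertex mean.

Numerical choices:

* **Tie-break.** Candidate $\bar d$ values within the polygonal
  circularity floor $(2\pi/N)^2 r_{ideal}$ of the minimum are ties,
  resolved to the central candidate.  The floor is the provable $\bar d$
  of an $N$-point polygon inscribed in a circle — sections of a faceted
  mesh can never score below it, so treating differences inside it as
  noise is principled, and it is orders of magnitude below any real bump
  signal.
* **Top/bottom sections** are cut at a 1% inset from the extremes (an
  exact extreme plane meets the mesh in a point, not a loop); the lofted
  skin is then extrapolated back over the insets to the full z-extent.
* **Ring area compensation.** Emitted rings use circumradius
  $r\sqrt{x/\sin x}$, $x = 2\pi/\mathrm{rings}$, so the ring *polygon*
  encloses exactly the intended area; resampled top/bottom loops are
  rescaled to preserve their polygon area.  Together with the inset
  extrapolation this makes the construction idempotent: re-lofting an
  ideal canal reproduces its spectrum to ~1e-6 relative, against the
  required 5% bound.
* Key sections are replaced by their equal-area circles by default
  (`circularize = FALSE` keeps the actual loops); centers and radial
  offsets are interpolated along depth with natural cubic splines
  (smooth transitions; exactly linear for collinear data, so tapered
  plans stay monotone).

## The SSD

With ascending eigenvalues and the shape-independent zero mode excluded,
$$\mathrm{SSD}(M,N) = \Big(\sum_{i=1}^{l} w_i\,
(\lambda_i - \mu_i)^2\Big)^{1/2}.$$
Weights come from the area-weighted histogram of $|K(x)|$ (discrete
Gaussian curvature by angle deficit over the barycentric 1-ring area —
the choice that makes Gauss–Bonnet $\sum K A = 2\pi\chi$ exact; a mixed
Voronoi area option gives better pointwise values on smooth meshes).
Bin $i$ of the averaged histograms of the two shapes (ascending
curvature) maps to eigenvalue rank $i$ (ascending frequency):
low-frequency eigenvalues encode global geometry, high-frequency ones
local detail, so detail-rich surfaces up-weight the high-frequency end.
The histogram spans $[0, q_{95}]$ with the top bin absorbing the clipped
tail (sliver-triangle guard); a floor of $1/(10l)$ prevents zero weights;
weights are normalized to sum 1.  The histogram-to-rank mapping is one
defensible reading of the curvature-weighting principle; it is isolated
behind `eigenvalue_weights()` so alternative schemes are drop-in.  `uniform`
and `kac` ($w_i \propto 1/i$) schemes are provided; with uniform weights
SSD reduces to the naive Euclidean distance over $\sqrt{l}$.

Raw spectra scale as $1/s$; `normalize_spectrum(., "area")` multiplies by
$\sqrt{\mathrm{area}}$, which is dimensionless and scale-invariant, and
is the default for shape comparison; raw and normalized spectra are
never mixed — mixing raises an error.

## Synthetic data: what it emulates and what it does not

`make_synthetic_canal()` is the package's stated world standing in for
µCT canal meshes: a tube 12 mm long tapering from a 1.2 mm coronal to a
0.35 mm apical radius (typical single-rooted prepared-canal dimensions),
a laterally curved axis (0.6 mm sinusoid), six C² Gaussian wall bumps of
0.15 mm (ledges/debris), and 0.02 mm i.i.d. radial surface noise
(segmentation roughness), clamped to 10% of the local radius to preserve
manifoldness.  `make_canal_pair()` models preparation as uniform radial
enlargement plus multiplicative damping of bump/noise amplitudes.
Everything is bitwise deterministic in the seed.

It does *not* emulate: multi-rooted/branching (Vertucci II–VIII)
topology, elliptical or C-shaped sections, dentin outer surfaces, voxel
artifacts, or registration error between pre/post scans.  A green test
therefore establishes correctness of the pipeline on single-canal,
genus-0, registered geometry — not clinical performance; in-vitro
cohort validation requires real specimens and is out of scope.

Tests and the acceptance suite run the generator at coarser resolutions
(e.g. 32 rings x 40 layers, ~1.3k vertices) than the generator defaults
purely for runtime; resolution is a fidelity knob, not part of the
stated world, and the downsampling-robustness criterion checks exactly
this insensitivity (first 20 area-normalized eigenvalues vary by <6%
across a 10x vertex-count range, against a 10% bound).

## Degenerate inputs and limitations

* Meshes must be closed, consistently oriented 2-manifolds; repair is
  out of scope (inward orientation is auto-flipped with a warning,
  everything else is an error naming the offending simplices).
* Section planes through mesh vertices are nudged by ~1e-9 of the
  height; exact-plane queries are therefore well-defined.
* Binary STL is float32 by format; one read/write cycle is a fixpoint,
  and ASCII formats carry 17 significant digits (exact double
  round-trip).
* The polyhedral $\bar d$ of a discretized circular section cannot fall
  below the polygon floor above; "circular section gives zero" holds in
  the continuum and for densely sampled loops (the tests use N = 4096).
* Thin, high-aspect canals stress the conditioning of $V$; symmetric
  diagonal equilibration is applied before factorization, and a
  conditioning error advises rescaling if factorization still fails.
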