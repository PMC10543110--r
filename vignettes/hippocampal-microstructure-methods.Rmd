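---
title: "Models and methods behind hippmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hippmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hippmap` maps hippocampal grey-matter microstructure in the hippocampus's own
coordinate system. This vignette explains each model in the chain, the
parameters that matter, the numerical choices behind the implementation, what
the synthetic-data generators do and do not emulate, and the package's known
limitations. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The Watson-NODDI signal model

The normalized diffusion signal at b-value $b$ and gradient direction $g$ is
modelled as three compartments,

$$E = f_{iso}\,E_{iso} + f_{ec}\,E_{ec} + f_{ic}\,E_{ic},
\qquad f_{iso}+f_{ec}+f_{ic}=1,$$

with an isotropic CSF term $E_{iso} = e^{-b\,d_{iso}}$, intra-cellular
"sticks" (diffusion only along the neurite axis $n$:
$e^{-b\,d_\parallel (g\cdot n)^2}$), and an extra-cellular zeppelin. Sticks and
zeppelin are linked orientationally by a Watson distribution
$W(\mu,\kappa) \propto e^{\kappa(\mu\cdot n)^2}$: $E_{ic}$ is the spherical
average of the stick signal under $W$, and $E_{ec} = e^{-b\,g^\top \bar D g}$
with the Watson-averaged zeppelin tensor
$\bar D = d_\perp I + (d_\parallel - d_\perp)\,\langle nn^\top\rangle_W$.
Orientation dispersion is reported on the bounded scale
$\mathrm{ODI} = (2/\pi)\arctan(1/\kappa)$.

Fixed parameters, with units and rationale:

* $d_\parallel = 1.1\times10^{-3}\ \mathrm{mm^2/s}$ — the grey-matter
  optimized axial diffusivity (the white-matter convention of
  $1.7\times10^{-3}$ biases grey-matter fits);
* $d_{iso} = 3.0\times10^{-3}\ \mathrm{mm^2/s}$ — free water;
* $d_\perp = d_\parallel(1-\nu_{ic})$, $\nu_{ic} = f_{ic}/(f_{ic}+f_{ec})$ —
  the tortuosity rule, stated with respect to the tissue-relative
  intra-cellular fraction (the convention of the original three-compartment
  model; the choice matters only when $f_{iso}>0$).

### Numerics of the Watson integrals

The integrand exponent $\kappa(\mu\cdot n)^2 - b\,d_\parallel(g\cdot n)^2$ is
a rank-2 quadratic form. Its in-plane eigenvalues are available in closed
form, which reduces every spherical integral to
$\int_{S^2} e^{a n_1^2 + b n_2^2}\,d\Omega
 = 2\pi\int_{-1}^{1} e^{\frac{a+b}{2}(1-u^2)}
   I_0\!\big(\tfrac{a-b}{2}(1-u^2)\big)\,du,$
a smooth 1D integral evaluated with fixed Gauss-Legendre quadrature (64 nodes
by default, 16 in the speed-oriented pipeline profile). Three safeguards:

* all exponents are scaled by $e^{-\kappa}$, so nothing overflows at any
  $\kappa$;
* numerator and denominator (the Watson normalization) share one quadrature,
  cancelling most quadrature error in their ratio;
* $e^{-x}I_0(x)$ uses the classical polynomial approximations (relative error
  $<2\times10^{-7}$), well below the $10^{-3}$ agreement the quadrature
  oracle test demands against a 10,000-point spherical brute force.

$E(b{=}0)=1$ holds exactly, antipodal symmetry
($\mu \leftrightarrow -\mu$) is exact, and the signal is monotone
non-increasing in $b$ — all asserted by tests.

### Fitting

`fit_noddi()` performs ordinary least squares on normalized magnitudes over
$(f_{iso}, f_{ic}, \kappa, \mu)$ with the diffusivities fixed. Fractions are
parameterized through logistic transforms ($f_{iso}$, and the tissue fraction
$\nu_{ic}$), $\kappa$ through a log transform, and $\mu$ through spherical
angles, making the problem unconstrained. Initialization is deterministic: a
coarse grid over $(f_{iso}, \nu_{ic}, \mathrm{ODI})$ crossed with the DTI
principal eigenvector of the b = 1000 shell; refinement uses BFGS with a
Nelder-Mead polish (default, `reltol` $10^{-12}$) or pure Nelder-Mead in the
pipeline profile. There are no random restarts, so fits are bit-reproducible.
The least-squares objective is a deliberate choice — the noise model a
magnitude-MRI fit should assume is acquisition-dependent, and the package's
recovery guarantees are stated in terms of simulate-then-fit accuracy rather
than likelihood fidelity.

DTI (`fit_dti()`) is an unweighted log-linear fit of the six tensor elements
plus $\ln S_0$ using only b = 0 and b = 1000 volumes (the single-shell regime
in which the tensor model is conventionally applied); negative eigenvalues
are clamped to zero and flagged.

## Laplace coordinates and axis fields

Each hippocampal axis coordinate $\psi \in [0,1]$ solves $\nabla^2\psi = 0$
on the voxel mask with $\psi = 0$ on the axis's source set, $\psi = 1$ on the
sink set, and no-flux conditions elsewhere. The discretization is the
6-connected finite-difference Laplacian with $1/h^2$ weights per axis;
omitting out-of-mask neighbours implements the reflecting boundary. The
default solver is a sparse direct factorization (Matrix), checked against the
residual tolerance (default $10^{-6}$, far below any downstream angular
sensitivity); a Jacobi fallback exists and fails loudly with its residual
when `max_iter` is exhausted. The discrete maximum principle
($\psi \in [0,1]$) is asserted on every solve.

Axis vectors are central differences (one-sided at mask edges) divided by the
voxel size — vectors live in physical mm space — then unit-normalized.
Voxels with gradient magnitude below $10^{-12}$ are flagged invalid and
excluded downstream, never zero-filled or imputed. On the curved-shell test
geometry the solved inner-outer field agrees with the analytic radial
direction of the cylinder to within 10 degrees at voxels at least half a
voxel clear of the source/sink bands; directly at the voxelized (staircase)
Dirichlet arcs the discrete field necessarily deviates more, which is a
property of the voxelization, not of the solver.

The boundary treatment (stencil, no-flux handling) is this package's own
documented choice; no claim is made that it is identical to any particular
surface-unfolding toolchain's internals.

## Orientation coherence

The cosine similarity $|\bar a\cdot\bar u|/(|\bar a||\bar u|)$ between an
axis vector and the fitted NODDI orientation is a scalar in $[0,1]$: 0 at 90
degrees, 1 at 0 degrees, with antipodal equivalence ($\mu$ and $-\mu$ are the
same orientation). The three similarities are treated independently; the
Laplace axis frame is close to orthonormal on a slab (where the Parseval
identity $cs_{AP}^2+cs_{PD}^2+cs_{IO}^2=1$ is asserted) but not in curved
regions, so no orthonormality is assumed in the analysis itself.

## Ribbon-constrained surface sampling

Each vertex's value is a weighted mean over the voxels its laminar prism
touches. The prism — a tangential patch around the vertex swept from the
inner to the outer sheet — is supersampled with a deterministic point grid
(default 3×3 tangential offsets × 6 laminar levels); each point's voxel
accumulates a weight equal to the hit count times a Gaussian in the distance
from the midthickness sheet with $\sigma = \text{thickness}/2$. The
thickness-to-$\sigma$ mapping is a documented, configurable choice
(`sigma_scale`); what matters scientifically is the qualitative behaviour —
voxels off the midthickness sheet are down-weighted more aggressively where
the lamina is thin — which the tests assert directly. Point-in-prism counting
approximates exact polyhedron-voxel intersection volumes; sampling is exactly
linear in the volume and exact for constant volumes, and vertices whose prism
misses the volume are returned as missing, propagating as NA through
group averaging.

## The torus spin test

Significance of a Spearman correlation between two unfolded maps cannot be
judged against an i.i.d. null: smooth maps have few effective degrees of
freedom. The spin test builds the null from transforms that preserve each
map's spatial autocorrelation. Because the unfolded domain is a rectangle
with periodic structure (and is poorly represented by a sphere), the
transform group used here comprises the isometries of the rectangular torus
that preserve the neighbour structure of the vertex grid: cyclic 2D shifts
composed with an optional 180-degree rotation. The identity is excluded and
resampled; the two-sided p-value uses the +1 permutation correction,
$p = (1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\})/(1+n_{perm})$, so $p = 0$ is
impossible. A lag-1 Moran-type statistic with periodic neighbours is verified
to be exactly invariant under every transform. Whether continuous
(interpolated) shifts or further rotations belong in the group is an open
modelling question; the discrete group is the documented choice here, and
type-I calibration under it is checked by Monte-Carlo (400 independent
smooth pairs at $\alpha = 0.05$, n_perm = 500, on a 32×16 grid — the
pipeline's own grid size).

FDR correction is Benjamini-Hochberg step-up across all map pairs as one
family, implemented via `stats::p.adjust` behind the `fdr_bh()` surface and
verified against the hand-computed worked example. Per-pair permutation
seeds derive from the sorted metric-name pair, making reports invariant to
map input order.

## OPNNMF

The vertices × subject-metrics matrix is normalized by z-scoring each metric
within hemisphere and shifting by the global minimum of all z-scored values,
giving a non-negative matrix with minimum exactly 0. The decomposition
minimizes $\|X - CC^\top X\|_F^2$ subject to $C \ge 0$ and (softly)
$C^\top C = I$, from deterministic NNDSVD initialization, with the
multiplicative update $C \leftarrow C \odot (XX^\top C) \oslash
(CC^\top XX^\top C)$.

Numerical choices:

* the update's overall scale is not self-stabilizing (scaling $C$ by
  $\alpha$ maps to $1/\alpha$), so each iterate is normalized by its spectral
  norm — the fixed ray is unchanged and, at an orthonormal fixed point, the
  normalization is the identity;
* the initial $C$ is floored at $10^{-12}$: the multiplicative rule cannot
  revive exact zeros, and NNDSVD produces many;
* a denominator floor of $10^{-12}$ guards divisions;
* convergence is declared on the relative change of the objective (default
  tolerance $10^{-5}$, cap 10,000 iterations; the monitored quantity is a
  documented choice);
* dead (all-zero) components at convergence are re-seeded once from the
  largest-residual vertex, keeping the requested k;
* the reported `recon_error` is the converged objective value. The returned
  $C$ has unit-norm columns for interpretability; when iteration stops short
  of orthonormality (typically when k exceeds the data's effective rank) the
  objective of the iterate — not a recomputation after rescaling — is the
  faithful error of the fitted projection, and it is what makes the
  empirical error-vs-k curve non-increasing.

Winner-take-all labels take the row argmax with ties to the lowest index.
Weights $W = C^\top X$ are z-scored within component rows for display.
Split-half stability fits both halves of a subject-level split (all metrics
and hemispheres of a subject travel together), row-normalizes each half's
$C$, forms the vertex-by-vertex cosine matrix $\hat C\hat C^\top$, and
correlates matched rows between halves; the mean ± SD over vertices × splits
is reported per k, alongside the full-data reconstruction error and its
gradient. Row normalization (true cosine similarity) is the adopted reading
of the similarity construction. Cross-hemisphere component matching is
provided as greedy maximal label overlap and is purely cosmetic.

## Subfield separability

Subfield-averaged (ODI, NDI, T1w/T2w) triples feed a multinomial logistic
classifier with an L2 penalty (glmnet ridge path at a single penalty;
`C = 1`, mapped as $\lambda = 1/(C\,n_{train})$ to mirror the common
inverse-regularization convention). Features are standardized with training
statistics because ridge penalties are scale-sensitive — a documented choice,
as is the default strength. Subjects are split 70/30 at the subject level
with hemispheres grouped; when fewer subjects are available the proportions
are preserved. The report carries the confusion matrix, per-class precision,
recall and $F_1 = 2PR/(P+R)$ (defined 0 when $P+R=0$), macro-$F_1$, and
accuracy (which equals micro-averaged recall, asserted as an identity). A
DTI-variant (FA, MD) classifier is available through the `features`
argument.

## What the synthetic data does and does not emulate

The generators produce: voxel domains (full slab, or a half-cylindrical
shell with configurable bend radius, default 8 voxels, so axis fields are
non-trivially oriented); per-voxel NODDI ground truth with five PD bands of
distinct neurite density and dispersion and per-band axis-aligned
orientations (a cartoon of subfield contrast and stereotyped circuitry);
multi-shell signals from the exact forward model with Gaussian (default) or
Rician noise at scale $1/\mathrm{SNR}$ — the default is Gaussian because the
appropriate magnitude-noise model for fitted data is acquisition-dependent;
unfolded multi-subject stacks with planted contiguous parcels, non-negative
loadings and smooth periodic Gaussian-filtered noise (64×32 = 2048 vertices
by default, close to the ~2000-vertex real surfaces; smoothing wraps
periodically, consistent with the torus assumption of the spin test);
correlated map pairs whose population Spearman correlation is set exactly via
the Gaussian rank-correlation relation $\rho_s = (6/\pi)\sin^{-1}(\rho_P/2)$;
and Gaussian subfield metric tables whose default class means mirror the
banding of the voxel generator.

They deliberately do not emulate: real hippocampal geometry (no folding,
no vertex-spacing distortion, no topological boundary structure), scanner
artifacts (eddy currents, distortion, bias fields), inter-subject anatomical
variability beyond parameter jitter, partial-volume mixtures at tissue
borders, or multi-fiber orientation structure. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as the
theory predicts under known ground truth — not that their outputs on real
scans would match any particular empirical map.

## Problem sizes and determinism

The test-suite and demo-pipeline sizes are the package's own choices for a
desk-scale, fully-reproducible run: an 8-subject demo cohort on a 32×16
unfolded grid and a 10×8×8-voxel slab, a 48-volume three-shell scheme
(6 b = 0 + 14 directions × 3 shells), 500 spin-test permutations (against
2500 for a production analysis — calibration is what matters at test scale),
a k = 2..5 stability sweep with 2 splits, and a fast NODDI fit profile
(Nelder-Mead, 16-node quadrature). All randomness flows from explicit seeds;
every generator saves and restores the global RNG state; reruns of the
pipeline under one root seed produce byte-identical artifacts, recorded as
MD5 hashes in the output manifest.

## Known limitations

* The NODDI fit is least-squares only; no Rician likelihood, and no soma or
  exchange compartments.
* Single-orientation microstructure: one Watson peak per voxel; crossing
  populations are not modelled.
* The Laplace boundary labelling on curved voxelized geometry is
  staircase-limited near source/sink bands.
* The spin-test transform group is discrete; maps whose autocorrelation is
  strongly non-stationary violate its exchangeability premise.
* OPNNMF stability is a reproducibility criterion, not a model-selection
  proof; the error-gradient curve is reported, and choosing k remains a
  judgement call.
* GIFTI I/O is not provided; surfaces and per-vertex maps interchange as
  CSV, volumes as NIfTI.
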