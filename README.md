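# hippmap

Surface-based mapping of hippocampal grey-matter microstructure.

The hippocampus folds a thin cortical mantle into a complex 3D shape, and its
subfields (subiculum, CA1–CA3, DG/CA4) differ in neurite architecture in ways
that volumetric voxel averaging smears out. `hippmap` implements an analysis
chain that works in the hippocampus's own coordinates instead: diffusion-MRI
microstructure models fitted per voxel, orientation coherence measured against
the intrinsic anterior–posterior (AP), proximal–distal (PD) and inner–outer
(IO) axes, and statistics computed on the unfolded 2D vertex grid where every
subject's surface is in register. It is aimed at neuroimaging methodologists
who want the full chain — model fit, axis fields, surface sampling, permutation
inference and matrix factorization — as tested, reusable R functions that run
end-to-end on synthetic data with known ground truth.

## What it computes

**Watson–NODDI** (`noddi_forward()`, `fit_noddi()`). The normalized
three-compartment diffusion signal

E = f_iso·E_iso + f_ec·E_ec + f_ic·E_ic,

with an isotropic CSF compartment E_iso = exp(−b·d_iso), intra-cellular
sticks, and an extra-cellular zeppelin, the latter two linked orientationally
by a Watson distribution W(μ, κ) with ODI = (2/π)·arctan(1/κ). Diffusivities
are fixed at the grey-matter values d_par = 1.1×10⁻³ mm²/s and d_iso =
3.0×10⁻³ mm²/s, with the tortuosity rule d_perp = d_par(1 − ν_ic). The Watson
spherical integrals are evaluated by an exact rank-2 eigenvalue reduction to a
1D Gauss–Legendre quadrature and verified against brute-force spherical
quadrature. DTI (`fit_dti()`) is a log-linear fit on the b = 1000 shell giving
FA, MD and the principal eigenvector.

**Laplace axis fields** (`solve_laplace()`, `gradient_fields()`). Per axis,
the potential ψ solves ∇²ψ = 0 on the voxelized hippocampus with source/sink
Dirichlet boundaries; unit gradients G_AP, G_PD, G_IO define the local axis
frame, and `similarity_volumes()` computes the per-voxel cosine similarity
|⟨a,μ⟩|/(|a||μ|) ∈ [0, 1] between the NODDI orientation and each axis.

**Surface sampling and group maps** (`sample_to_midthickness()`,
`average_maps()`). Volumes are sampled onto the midthickness surface with a
ribbon-constrained, thickness-scaled Gaussian weighting (σ = thickness/2) and
averaged vertex-wise across subjects in unfolded space.

**Torus spin test** (`spin_test()`, `all_pairs_report()`). Spearman
correlations between unfolded maps are tested against spatial-
autocorrelation-preserving nulls built from the isometries of the rectangular
torus (periodic 2D shifts × 180° rotation), with Benjamini–Hochberg FDR
across all map pairs.

**OPNNMF parcellation** (`opnnmf_fit()`, `stability_analysis()`). Orthogonal
projective NMF, min ‖X − CCᵀX‖² s.t. C ≥ 0, CᵀC = I, via NNDSVD
initialization and the multiplicative update C ← C ⊙ (XXᵀC) ⊘ (CCᵀXXᵀC),
with winner-take-all labels, row-z-scored weights, and split-half stability
(Pearson correlation between matched rows of the two halves' vertex-by-vertex
cosine-similarity matrices CCᵀ).

**Subfield separability** (`subfield_separability()`). A multinomial
L2-regularized logistic classifier on subfield-averaged (ODI, NDI, T1w/T2w)
with subject-level 70/30 splits, confusion matrix and per-class
F1 = 2PR/(P+R).

**Synthetic data** (`make_voxel_domain()`, `simulate_dwi()`,
`make_unfolded_dataset()`, `make_correlated_map_pair()`,
`make_subfield_table()`). Every input the chain needs is generated with known
ground truth, so recovery is testable without any imaging data.

## Worked example

Simulate one subject on a slab domain, fit NODDI, and measure how the fitted
orientation aligns with the hippocampal axes:

```r
library(hippmap)

domain <- make_voxel_domain(c(12, 8, 8), "slab")
axes   <- gradient_fields(laplace_coordinates(domain))
truth  <- make_ground_truth_params(domain, axes, seed = 1)
scheme <- make_scheme(c(1000, 2000, 3000), n_dir = 30, n_b0 = 6)
dwi    <- simulate_dwi(truth, scheme, snr = 30, seed = 1)

vox <- which(domain$mask)[200]               # a voxel in the Sub-like PD band
sig <- apply(dwi, 4, function(v) v[vox])     # that voxel's 96 signals
fit <- fit_noddi(sig, scheme)
fit
#> NODDI fit (residual 0.332, converged):
#> NODDI parameters: f_iso=0.029 f_ic=0.586 f_ec=0.385 odi=0.404 (kappa=1.36)
#>   mu=(0.999, 0.008, -0.037)

g_ap <- sapply(1:3, function(d) axes$G_AP[, , , d][vox])
g_io <- sapply(1:3, function(d) axes$G_IO[, , , d][vox])
cosine_similarity(g_ap, fit$params$mu)
#> [1] 0.999
cosine_similarity(g_io, fit$params$mu)
#> [1] 0.037
```

The voxel's planted truth is NDI 0.58, ODI 0.42, with neurites oriented along
the long (AP) axis; from a single SNR-30 simulated scan the fit recovers
NDI ≈ 0.59 and ODI ≈ 0.40, and the fitted orientation is essentially parallel
to G_AP (cosine similarity 0.999) and orthogonal to the laminar axis (0.037) —
the scalar orientation-coherence readout the package is built around.

The whole chain — simulation, fitting, axis fields, surface sampling,
averaging, spin-test correlations, subfield classification and OPNNMF with
stability — runs from one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "demo", seed = 1))
head(res$correlation$pairs[order(res$correlation$pairs$q), ], 3)
#>    metric_a metric_b        rho           p           q rejected
#> 1     cs_AP    cs_IO -0.5352007 0.001996008 0.009314704     TRUE
#> 21       fa      odi -0.7697510 0.001996008 0.009314704     TRUE
#> 22       fa   t1wt2w  0.7498011 0.001996008 0.009314704     TRUE
```

Further down the same report, neurite density tracks the synthetic myelin
proxy (ndi–t1wt2w ρ = 0.95) and anti-correlates with MD (ρ = −0.98) — the
structure of the generator, recovered end-to-end through noisy simulated
scans. A thin
command-line front-end lives in `inst/scripts/run_pipeline.R`.

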