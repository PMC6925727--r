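# canalssd — Steklov-spectrum shape evaluation of root canal preparations

`canalssd` scores the quality of endodontic root canal preparation by
comparing the prepared canal, segmented from µCT as a closed triangle
mesh, against an automatically constructed **ideal benchmark canal** —
not by the classical slice-integrated volume/area/transportation scalars
(which it also computes, for reference), but by a spectral shape
distance.

It is aimed at researchers evaluating instrumentation systems on µCT
data, and at anyone needing a self-contained boundary-element Steklov
(Dirichlet-to-Neumann) eigensolver for closed surface meshes in R.

## The method

For a solid Ω with boundary Σ, the Steklov problem

    Δu = 0 in Ω,   ∂u/∂n = λ u on Σ

defines the spectrum 0 = λ₀ < λ₁ ≤ λ₂ ≤ … of the Dirichlet-to-Neumann
map (units mm⁻¹) — an *extrinsic* shape descriptor sensitive to
concavity and volume.  The package assembles the Galerkin
boundary-element matrices V (single layer), K, K* (double layer and
adjoint), D (hypersingular, regularized curl form) and G (mass), and
solves the symmetric Schur-complement eigenproblem

    [ D + (½G + K)ᵀ V⁻¹ (½G + K) ] u = λ G u.

The ideal canal is lofted through the most circular ("key") cross
sections of each canal third, selected by the mean radial deviation
d̄ from the equal-area circle radius r_ideal = √(A/π).  The **Steklov
spectrum distance**

    SSD = sqrt( Σᵢ wᵢ (λᵢ − μᵢ)² ),  i = 1..l

weights eigenvalue ranks by the area-weighted histogram of absolute
Gaussian curvature: detail-rich surfaces up-weight the high-frequency
end.  Lower SSD to the ideal = better preparation.

## Worked example

```r
library(canalssd)

## a synthetic canal pair: 12 mm canal, tapering 1.2 -> 0.35 mm radius,
## curved axis, 6 wall bumps; "preparation" enlarges by 0.25 mm and
## removes 80% of the bump amplitude
params <- synth_canal_params(rings = 32, layers = 40, noise_sd = 0, seed = 11)
pair   <- make_canal_pair(params, enlargement = 0.25, smoothing = 0.2)

report <- evaluate_preparation(pair$pre, pair$post, l = 20, rings = 32,
                               slice_N = 100)

cat(sprintf("SSD(post, ideal)    : %.4f\n", report$ssd))
cat(sprintf("SSD(pre, post)      : %.4f\n", report$ssd_pre_post))
cat(sprintf("volume pre -> post  : %.2f -> %.2f mm^3\n",
            report$volume$pre, report$volume$post))
cat(sprintf("area   pre -> post  : %.2f -> %.2f mm^2\n",
            report$area$pre, report$area$post))
cat(sprintf("mean transportation : %.4f mm over %d levels\n",
            report$transportation$mean, report$transportation$levels_used))
```

which prints:

```
SSD(post, ideal)    : 0.0119
SSD(pre, post)      : 0.3286
volume pre -> post  : 25.47 -> 41.78 mm^3
area   pre -> post  : 64.53 -> 85.44 mm^2
mean transportation : 0.0155 mm over 100 levels
```

Reading: the prepared canal sits very close to its ideal benchmark
(SSD 0.012 on area-normalized spectra, versus 0.329 between the raw and
prepared shapes), volume and area grew as expected under even
enlargement, and the centerline moved only 16 µm on average — a good
preparation.  The same numbers are produced by the CLI:

```sh
Rscript inst/exec/canalssd evaluate pre.off post.off --l 20 --out report.json
Rscript inst/exec/canalssd spectrum canal.off --l 20 --normalization area
Rscript inst/exec/canalssd synth --seed 42 --out canal.off
```

Lower-level pieces are exposed individually: `read_mesh()`/`write_mesh()`
(OFF/PLY/STL/OBJ), `assemble_operators()`, `solve_steklov()`,
`normalize_spectrum()`, `extract_cross_section()`,
`select_key_sections()`, `loft_ideal_canal()`, `curvature_histogram()`,
`eigenvalue_weights()`, `ssd()`, `build_slice_stack()`,
`center_transportation()`, `iccg_solve()`, and the fixture generators
`make_icosphere()`, `make_cylinder()`, `make_cone()`,
`make_synthetic_canal()`, `make_canal_pair()`.

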