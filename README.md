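# xdtomo

Simulation and reconstruction toolkit for **pencil-beam X-ray diffraction
tomography (XDT)** — the tomographic modality that reconstructs the spatially
resolved coherent-scatter form factor `f(x, y, q)` of a 2D object slice
instead of its attenuation map, and can do so inside a **region of interest
(ROI)** from truncated projections, at a fraction of the scan time and dose
of a full scan.

It is aimed at researchers prototyping table-top diffraction-tomography
systems and interior-reconstruction algorithms: everything runs on synthetic
phantoms with known ground truth, from detector frames to material maps.

## The measurement and the model

A monochromatic pencil beam (energy E = 8 keV, wavelength λ = hc/E) scans an
object on translation offsets `s` (1 mm steps) and rotation angles `φ` (46
angles of 4°). Photons scattered at depth `t` along the beam with momentum
transfer `q = sin(θ/2)/λ` land on a detector ring of radius

    r = (D − t) · tan θ(q),        D = 120 mm,

so each azimuthally averaged frame mixes depth and momentum transfer. The
scan is the 3D sinogram `g(s, φ, r)`; in `(t, 1/q)` coordinates the
contributions to a radial bin follow straight fan rays with a virtual vertex
at the detector, which makes the 2D scan equivalent to a 3D circular
parallel-fan-beam CT. The package provides:

* `project()` / `build_forward_operator()` — the linear forward model
  `g = H f` with an exact adjoint (machine-precision duality),
* `fdk_reconstruct()` — global reconstruction by a modified
  Feldkamp–Davis–Kress filtered backprojection for the parallel-fan
  geometry (`fbp_per_q()` is the large-distance per-q limit),
* `ml_tv_reconstruct()` — interior reconstruction from ROI-truncated
  counts by Poisson maximum-likelihood (MLEM) updates with total-variation
  regularization, on the full object grid,
* `train_svms()` / `classify_volume()` — material identification from
  reconstructed spectra with calibrated one-vs-rest SVMs,
* `scan_dose()` / `dose_reduction()` — pencil-beam Beer–Lambert absorbed
  dose of global vs interior scan plans.

## Worked example

```r
library(xdtomo)

geom    <- xdt_geometry()                    # 8 keV, D = 120 mm, 46 angles
phantom <- build_phantom("phantom4")             # 32 mm disk, 14 mm central ROI
object  <- phantom_to_object(phantom)        # ground-truth f(x, y, q)

plan_g <- plan_global(phantom, geom)         # 33 offsets x 46 angles
plan_i <- plan_interior(phantom, geom)       # 15 offsets cross the ROI

H      <- build_forward_operator(geom, object, plan_g)
sino_g <- simulate_scan(object, geom, plan_g, target_counts = 1e4,
                        seed = 1, operator = H)
sino_i <- truncate_to_roi(simulate_scan(object, geom, plan_i,
                                        target_counts = 1e4, seed = 2,
                                        operator = H), phantom$roi)

grid  <- list(n = 64, pitch_mm = 0.5, q_grid = object$q_grid)
vol_g <- fdk_reconstruct(sino_g, geom, grid)
rec   <- ml_tv_reconstruct(sino_i, H, recon_params())
rec
#> XDT ML+TV reconstruction: 168 iterations (converged), final objective -8.6685e+09
#> XDT object volume: 64 x 64 spatial (0.5 mm pitch) x 24 q-bins (0.050..0.250 1/A)

nrmsd(rec$volume, vol_g, phantom$roi)        # interior vs global, % of range
#> [1] 15.55
```

The interior reconstruction recovers the material fingerprints inside the
ROI (per-material mean spectra correlate with the library at r = 0.94–0.999)
and reproduces the global material map on ~97 % of ROI pixels, while using
15 of 33 translation offsets. The NRMSD between the two reconstructions is
dominated by their different resolution characteristics — see the methods
vignette (`vignettes/xdt-methods.Rmd`) for the analysis.

On the tissue phantom, the dose comparison is:

```r
ph   <- build_phantom("tissue")                # 23 mm fat/muscle, 6 mm ROI
dg   <- scan_dose(ph, plan_global(ph, geom))
di   <- scan_dose(ph, plan_interior(ph, geom))
dose_reduction(dg, di, "total")              # percent
#> [1] 78.84
roi_dose_ratio(dg, di)
#> [1] 0.994
```

`run_pipeline(xdt_config(), mode = "phantom")` chains all stages and writes
a JSON summary; a thin command-line front end lives in `inst/cli/xdt.R`.

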