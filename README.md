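# panelpet

Desk-scale simulation and reconstruction toolkit for design studies of
**flat-panel time-of-flight PET scanners**.

Modern TOF detectors with a coincidence time resolution (CTR) below
100 ps localize each annihilation to a few centimetres along its line of
response, which relaxes the requirement of full angular coverage. That
opens the door to scanners built from four flat detector panels — far
cheaper in scintillator and photodetectors than a full ring — at the
price of limited-angle artifacts that the TOF information must suppress.
`panelpet` lets you quantify that trade-off: it simulates such scanners
(and a conventional 78 cm-bore clinical ring as the reference) end to
end, and evaluates them with the standard PET performance metrics.

The chain, all in one package:

* **Monte Carlo simulator** — back-to-back 511 keV photon pairs with
  0.5° non-colinearity, Poisson decay timing, Woodcock transport with
  Klein–Nishina Compton scattering through analytic phantoms (NEMA IQ
  body phantom, point-source grids, normalization cube, NECR cylinder,
  hot-rod disc), and crystal-level interaction physics including
  inter-crystal scatter.
* **Digitizer & coincidence sorter** — crystal- or 5×5-submodule
  readout with winner-take-all / energy-centroid positioning, 10%
  energy resolution at 511 keV, 435–585 keV window, configurable CTR,
  sliding 2 ns window with killAll multiple-coincidence policy and
  truth labels (true / scattered / random).
* **Reconstruction** — list-mode MLEM,
  `x_j ← (x_j/s_j) · Σ_i a_ij / Σ_k a_ik x_k`, with an exact Siddon
  projector, crystal-aperture footprint modelling, Gaussian TOF kernel
  (σ = c·CTR/(2√(2 ln 2))/2, ±3σ), Monte Carlo sensitivity image and
  Gaussian post-filters.
* **Metrics** — 3D Gaussian PSF fits (per-axis FWHM), NEMA NU 2-2018
  percent contrast / background variability with homogeneous-cube
  normalization correction, axial sensitivity profiles (kcps/MBq),
  `NECR = T²/(T+S+R)` and `NECR_TOF = (2D/cΔt)·NECR`, and SSIM.

## Worked example

Scanner configurations use the naming scheme
`CS<cross-section>_L<length>_CTR<ps>[_pitch<p>][submod]`:

```r
library(panelpet)
set.seed(1)

sc  <- build_scanner("CS3_L10_CTR75")   # 4 panels, 40,000 3x3x10 mm crystals
ref <- build_scanner("reference")       # 19-sector ring, 60,800 crystals
total_crystal_volume(sc$geometry)       # 3.6  dm^3
total_crystal_volume(ref$geometry)      # 12.45184 dm^3  -> 28.9% relative

# simulate a point source in air at the FOV center and digitize it at
# crystal and at submodule readout level
ph  <- analytic_phantom(list(prim_sphere(c(0, 0, 0), 0.1,
                                         activity_kBq_mL = 16710)), "air")
acq <- run_acquisition(ph, sc$geometry, n_decays = 1e5)
n_cry <- nrow(process_acquisition(acq, sc$geometry,
                                  coincidence_policy(level = "crystal")))
n_sub <- nrow(process_acquisition(acq, sc$geometry,
                                  coincidence_policy(level = "submodule")))
c(n_cry, n_sub, n_sub / n_cry)
#> [1] 3695.000000 6506.000000    1.760758
```

The submodule readout recovers inter-crystal scatter, almost doubling
sensitivity — one of the design effects the package reproduces. A full
resolution measurement (simulate a 0.1 mm source at (37, 0, 0) mm in a
low-activity background cube, reconstruct with 30 TOF-MLEM iterations at
0.8 mm voxels, fit the 3D Gaussian):

```r
set.seed(108)
res <- panelpet:::reconstruct_point_source(
  sc$geometry, sc$policy, c(37, 0, 0), n_true_target = 4e5)
round(res$fit$fwhm, 2)    # FWHM (x, y, z) in mm, ~3.5 min
#> [1] 1.91 1.80 1.90
```

compared with ~1.9 mm reported for this configuration at full
statistics. Higher-level orchestration (per-study CSV + provenance JSON,
the `exec/panelpet` CLI wrapper):

```r
run_study("sensitivity", scanner = "CS3_L10_CTR75", seed = 1,
          out_dir = "results/", scale = 0.1)
```

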