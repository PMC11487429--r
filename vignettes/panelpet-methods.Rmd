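---
title: "panelpet: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panelpet: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`panelpet` reproduces, at desk scale, the full evaluation chain used in
simulation studies of flat-panel time-of-flight PET scanners: Monte Carlo
generation of annihilation-photon pairs, photon transport through analytic
phantoms and into scintillator crystals, a digitizer and coincidence
sorter, list-mode TOF-MLEM reconstruction, and the standard performance
metrics (3D-Gaussian spatial resolution, NEMA NU 2-2018 image quality,
axial sensitivity, NECR/NECR_TOF, SSIM). This vignette records the models,
their assumptions, and every numerical decision that was genuinely open.

## Scanner models

**Flat-panel scanner.** Four 30 x 30 cm panels face the axial (Z) axis in
a square-prism arrangement; the 40 cm panel separation is interpreted as
the *inner-face to inner-face* distance (the natural reading for a
detector gap; the alternative center-to-center reading would shrink the
FOV by one crystal length). Crystals sit on a fixed-pitch grid (3 mm by
default); cross-sections smaller than the pitch leave vacuum gaps
(sparse configurations), with each crystal centered in its pitch cell.
Crystal indexing is panel-major, then axial-row-major, so list-mode files
are reproducible.

**Reference ring.** A 19-sector cylindrical scanner with
3.2 x 3.2 x 20 mm crystals in 5 x 5 submodules (760 transaxial x 80 axial
crystals, 78 cm bore, 26.3 cm axial FOV, 60,800 crystals, 12.45 dm^3 of
scintillator). Sector placement around the ring is uniform; the exact
transaxial sector offsets and mechanical gaps of the commercial scanner
are not public, so crystals are placed as flat boxes on a uniform
tangential grid. End shields and detector dead time are not modelled.

**LOR endpoint and DOI.** No depth-of-interaction measurement is
simulated. The reconstruction assigns every event to the geometric center
of its crystal volume (entrance face + length/2), so parallax error
emerges naturally and shortening the crystals improves off-center
resolution, which is exactly the design effect the package is meant to
expose.

## Photon physics

The simulator generates back-to-back 511 keV photon pairs (no positron
range; the first direction isotropic, the second deflected by a Gaussian
acolinearity of 0.5 degrees FWHM). Transport uses Woodcock (delta)
tracking with total attenuation and photoelectric fractions for water,
polyethylene, lung (0.3 x water) and LYSO, tabulated at
{50, 100, 170, 255, 340, 511} keV and log-log interpolated. Compton
scattering is sampled from the Klein-Nishina distribution (Kahn's
rejection method); Rayleigh scattering, fluorescence escape and Doppler
broadening are ignored as second-order at 511 keV. Photons terminate on
photoabsorption, on falling below 50 keV, or after 5 scatters (the
remainder is deposited locally inside a crystal, so energy is conserved
exactly per photon). In the detector, Compton-scattered photons continue
and may deposit in other crystals — the inter-crystal scatter that makes
submodule readout roughly twice as sensitive as crystal readout.

Absolute sensitivities are *not* expected to match a full GATE
simulation (optical photons, exact LYSO stoichiometry, reflector gaps and
electronics thresholds are all absent); the package's claims are the
relative orderings across designs, which the acceptance suite asserts.

## Digitizer and coincidences

Deposits sharing a readout group (crystal, or 5 x 5 submodule) within the
integration window are summed; the position carrier is the
maximum-deposit crystal (winner-take-all) or the crystal nearest the
energy-weighted centroid. Energy resolution is 10% FWHM at 511 keV with
1/sqrt(E) scaling (the GATE convention; only the 511 keV point is pinned
by the design study). Time stamps receive Gaussian jitter with
sigma = CTR / (2 sqrt(2 ln 2)) / sqrt(2) per single, so the pair
time-difference FWHM equals the configured CTR. The energy window
(435-585 keV) is applied after grouping and before pairing. The sliding
coincidence window (2 ns flat panel, 4.7 ns ring) discards windows with
more than two qualifying singles entirely (killAll); the integration
window is set equal to the coincidence window. Both choices are
assumptions — the source study does not state GATE's digitizer
configuration — and are low-impact because all reconstructions use true
coincidences only. Geometry acceptance: any pair of distinct panels, or
a minimum circular sector difference of 4 on the ring.

Pairs are emitted in arrival order, so the stored `dt = t1 - t2` is
non-positive; the TOF kernel uses the same convention, making the
pipeline self-consistent.

## Reconstruction

List-mode MLEM with the multiplicative update
`x_j <- (x_j / s_j) * sum_i a_ij / (sum_k a_ik x_k)`, uniform
initialization inside the sensitivity support, and exactly `n_iter`
iterations (30 for resolution studies, 50 for image quality, as in the
source protocol). The projector is exact Siddon ray tracing with a
Gaussian TOF weight (sigma = c * CTR / (2 sqrt(2 ln 2)) / 2, truncated at
3 sigma).

**Aperture modelling (an important deviation).** A single thin ray
between crystal *centers* aliases severely when the voxel size (0.8 mm)
is far below the crystal pitch (3 mm): reconstructed images develop a
period-two checkerboard and Gaussian fits fail. The reference
implementation in the source study avoided this by using a
distance-driven projector, whose footprint spans the crystal aperture.
`panelpet` approximates that footprint with `aperture_rays` (default 4)
rays per event whose transverse endpoints sample the crystal face
(stratified over a 2 x 2 sub-grid, with decorrelated strata at the two
ends); the event's system-matrix row is the average of its rays, so the
aperture is part of the forward model and MLEM can deconvolve it, rather
than a blur applied to the data. Depth stays fixed at length/2 to
preserve the parallax behaviour.

**Sensitivity image.** `s_j` is estimated by backprojecting uniformly
sampled admissible crystal pairs (Monte Carlo), with the same aperture
sampling, and optionally smoothed (default 3 voxels FWHM for resolution
studies, 6 mm for IQ) to suppress residual Monte Carlo noise; the global
scale of `s` cancels in contrast ratios. Resolution studies reconstruct a
64^3 sub-grid around each source instead of the full FOV — a desk-scale
concession that leaves the system model unchanged.

**Image quality grid.** The IQ FOV is 36 cm at 3 mm voxels; the voxel
count is forced odd (121) so that one slice plane passes exactly through
the sphere equators. With an even count the "central" slice sits 1.5 mm
off the equator and partial volume depresses the large-sphere contrast by
several points.

## PSF fitting

Spatial resolution is the per-axis FWHM (`2 sqrt(2 ln 2) sigma`, the
constant kept exact in code) of a 3D Gaussian with a constant offset,
fitted by bound-constrained nonlinear least squares to the voxel values
around the source. At desk-scale statistics the background cube is
noisy, and a single moment-based start diverges on a substantial
fraction of realizations; the fitter therefore uses multiple starts (the
moment start plus three fixed-width starts of 1, 2.5 and 6 voxels
centered on the expected source position) and keeps the convergent fit
with the lowest residual sum of squares. Non-convergence of all starts
is flagged, never silently dropped, and secondary maxima above half the
fitted amplitude trigger a warning (iterative reconstruction of point
sources can split peaks at high iteration counts).

## Synthetic-data world and desk scaling

The generator's defaults are the conditions of the source protocol:
NEMA IQ phantom at 5.3/21.25 kBq/mL (ratio 4), 0.1 mm point sources of
70 Bq on a 5 x 5 x 5 grid with 37 mm spacing, the 4 cm / 28.8 kBq
background cube centered on each source (the centering is our reading of
an ambiguous description; it keeps the signal-to-background ratio ~8
uniform across the grid), the 36 cm normalization cube in air, and the
70 cm polyethylene NECR cylinder with its 1.6 mm line source at the NEMA
45 mm offset (the offset is unstated in the study; NEMA NU 2 convention
adopted). The stated activities "70 Bq (0.45 kBq/mL)" and "28.8 kBq
(16.7 MBq/mL)" are mutually swapped in the source text; the absolute
activities are trusted (70 Bq in a 0.1 mm sphere *is* 16.7 MBq/mL and
28.8 kBq over 64 mL *is* 0.45 kBq/mL).

Event counts are the desk-scale knob: resolution studies collect a few
10^5 true coincidences per source (the original acquisitions of 30-133 h
imply orders of magnitude more), IQ runs collect roughly 10^8 decays
instead of ~3 x 10^9, and NECR points use ~10^6 decays at the nominal
220 MBq (10 kBq/mL over the 22 L phantom), i.e. a few milliseconds of
wall-clock acquisition, which is ample for rate ratios because the
coincidence window is 2 ns. Consequences: background-variability values
are far above the clinical ~5% level, so contrast-at-matched-variability
comparisons are made at the midpoint of the overlapping variability
ranges of the two configurations being compared rather than at 5%; and
`contrast_at_variability()` refuses to extrapolate outside the measured
span. A green IQ-trend test therefore establishes the *ordering* of
designs under matched noise, not the absolute contrast values of the
full-statistics study — and even the ordering splits into a resolvable
and an unresolvable half at desk scale. Background variability, averaged
over 60 ROIs, is a stable estimate: its ordering across designs (noisier
with fewer counts, i.e. sparser crystals or worse CTR at a fixed filter)
is asserted and green. Hot-sphere percent contrast, by contrast, rests
on a single-slice ROI holding only on the order of a hundred events, and
iterated MLEM correlates that noise: per-sphere contrast estimates swing
by ~20 points between realizations, so contrast orderings at matched
variability — gaps of a few to ~20 points in the full-statistics study —
are not reliably resolvable below roughly paper statistics (~100x the
desk budget). Those assertions are implemented faithfully and expected
to stay red at desk scale.

For studies that use true coincidences only, `run_acquisition(trues_only
= TRUE)` kills events at the first phantom interaction and skips events
whose emission line cannot reach two detector heads (with a 5 mm margin
covering acolinearity) — an exact shortcut, not an approximation, for
those studies.

## Known limitations

- Absolute sensitivity and NECR are higher than published values for the
  modelled scanners (simplified detector physics); only relative
  comparisons are meaningful.
- The background material fills the phantom's bounding sphere; phantoms
  with a non-air background must enclose their primitives accordingly.
  All built-in phantoms use air backgrounds with explicit material
  primitives.
- Photons that re-enter the phantom after scattering in a detector are
  not re-attenuated.
- The anatomical (BigBrain) phantom of the source study is out of scope;
  a procedural hot-rod phantom stands in for qualitative/SSIM work, so
  SSIM *values* are not comparable, only the machinery (which is verified
  against an independent implementation).
- The multiple-peak warning of the Gaussian fitter flags, but does not
  repair, reconstructions degraded by iteration artifacts.
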