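# nanotopo

Nanometer-precision 3D mapping of membrane receptor topography from biplane
single-molecule localization microscopy (SMLM/dSTORM).

T-cell receptors such as CD4 and CD45 live on a surface that is anything but
flat: microvilli-like protrusions put receptors at axial levels ~100–200 nm
apart, which a 2D super-resolution image silently projects onto one plane.
`nanotopo` recovers the axial coordinate of every localization from the
*intensity ratio* of a biplane detection scheme and turns the resulting 3D
point clouds into quantitative statements about where receptors sit on the
membrane landscape. It is written for microscopists analyzing two-channel
rapidSTORM/CSV localization tables, and for method developers who want a
fully synthetic, ground-truthed test bed for axial SMLM pipelines.

## The method

Emission is split 50/50 onto two cameras focused at different depths. Spots
are fitted in both channels with a Gaussian of **fixed** FWHM (300 nm), so
defocus translates into fitted intensity. For each emitter appearance
matched across channels, the axial observable is the normalized contrast

    γ = (I₂ − I₁) / (I₁ + I₂) ∈ [−1, 1],

independent of the molecule's absolute brightness. A calibration scan
(known stage z) yields γ(z): the running median in 25 nm bins is fitted by
a high-order polynomial, and the strictly monotone part becomes a lookup
table that is inverted by linear interpolation — no extrapolation, ever.

Around that core the package provides, each as plain functions on tibbles:

* **loc_io** — rapidSTORM-text / CSV localization reading, writing, and the
  500-photon intensity filter (`read_localizations()`, `validate_table()`);
* **spotfit** — an optional fixed-FWHM Gaussian spot fitter for raw frames
  (`detect_candidates()`, `fit_spot_fixed_fwhm()`, `localize_stack()`);
* **calibration / zlocalize** — LUT construction and inversion, channel
  registration, framewise greedy nearest-neighbor pairing at 500 nm,
  refractive-index rescaling;
* **postprocess** — fiducial-free axial drift correction (polynomial in
  time over 500-frame windows), sample-tilt plane removal (drift first,
  then tilt), and track-based localization precision (75 nm track budget);
* **quantify** — 20 nm z-stacks, 2 × 2 µm ROI tiling (> 75% mask
  coverage), per-ROI bi-Gaussian fits and the derived descriptors

      z_w = (m₂ + FWHM₂/2) − (m₁ − FWHM₁/2),   p-p = |m₂ − m₁|,
      Δ_FWHM = |FWHM₁ − FWHM₂|,   FWHMᵢ = 2.355 sᵢ,

  plus population fits (mono-/bi-Gaussian, exponential) with ranges
  reported as µ ± FWHM/2 rounded to integer nm;
* **texture** — the GLCM homogeneity score for fluorescence images
  (ISODATA background zeroing, four directions, inverse-difference weight);
* **synthdata** — calibration scans, blinking membrane emitters on a
  two-level surface with drift/tilt/photon noise, raw frame rendering, all
  with per-appearance ground truth;
* **pipeline** — `run_pipeline()` chaining everything with a localization
  bookkeeping ledger, plus a thin CLI at `inst/cli/nanotopo.R`.

Fitted objects support `tidy()`/`glance()` and `autoplot()`.

## Worked example

A dispersed-receptor scenario (half the emitters on 150 nm protrusion tips,
half on the membrane base), imaged synthetically and quantified end to end:

```r
library(nanotopo)
library(dplyr)

om  <- optical_model()                      # ∓200 nm planes, w = 300 nm, 2000 photons
lut <- build_axial_lut(simulate_calibration_scan(om, noise = "none"))

sim   <- simulate_membrane_locs(surface_model(fraction_on_tips = 0.5), om,
                                n_frames = 4000, emitters_per_frame = 6,
                                extent = 12000, seed = 42)
pairs <- pair_localizations(sim$transmitted, sim$reflected)
locs  <- correct_refractive_index(assign_z(pairs, lut, quiet = TRUE))

zs   <- render_zstack(locs)                 # 20 nm voxels
d    <- dim(zs$counts)
mask <- matrix(TRUE, d[1], d[2])            # full field as master ROI
attr(mask, "pixel_size") <- 20; attr(mask, "origin") <- zs$origin[1:2]

rois <- quantify_rois(zs, tile_rois(mask)) |> filter(converged)
rois |> select(roi, m1, s1, m2, s2, z_w, p_p, delta_fwhm) |> head(4)
#>     roi     m1    s1    m2    s2   z_w   p_p delta_fwhm
#> 1     1  0.660  25.9  152.  25.7  212.  151.      0.505
#> 2     2  0.904  28.6  140.  23.3  200.  139.     12.3
#> 3     3 -2.58   24.5  151.  29.0  217.  154.     10.6
#> 4     4 -1.65   27.4  155.  27.1  221.  156.      0.755

fit_population(rois$z_w, "mono_gaussian", bin_width = 10)
#>   component    mu sigma lower upper
#> 1         1  213.  11.7   199   227
```

Each ROI's axial histogram resolves the two injected membrane levels: the
bi-Gaussian means sit near 0 and 150 nm, the peak-to-peak distance near the
injected 150 nm, and z_w ≈ 215 nm is the full axial spread including both
component widths. A tip-clustered scenario (`fraction_on_tips = 1`)
collapses to a single level: mean z_w drops to ~80 nm and p-p to ~35 nm,
reproducing the qualitative contrast between a receptor confined to one
topographical level and one spread over the membrane landscape.

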