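---
title: "Intensity-ratio axial localization and receptor nanotopography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-ratio axial localization and receptor nanotopography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(nanotopo)
library(dplyr)
```

## The measurement problem

Single-molecule localization microscopy (SMLM/dSTORM) resolves membrane
receptors laterally with ~10 nm precision, but a 2D image flattens the cell
surface: receptors sitting on the tips of microvilli-like protrusions and
receptors on the membrane base project onto the same plane. Deciding whether
an apparent "cluster" is a lateral density feature or simply the tip of a
protrusion requires the axial (z) coordinate at comparable precision.

`nanotopo` implements an intensity-ratio biplane scheme for that purpose.
The emission of each blinking fluorophore is split 50/50 onto two detectors
focused at slightly different depths. Every spot is fitted in both channels
with a 2D Gaussian of *fixed* width (FWHM 300 nm by default); defocus then
shows up not in the fitted width but in the fitted intensity. The axial
observable per matched appearance is the normalized contrast

$$\gamma = \frac{I_2 - I_1}{I_1 + I_2} \in [-1, 1],$$

which is independent of the absolute photon yield of the molecule, because
any common photometric factor cancels in the ratio. A calibration scan maps
$\gamma$ to z once per optical configuration.

Because only the two fit intensities are needed — no aperture photometry and
no exclusion zone around each spot — the method tolerates the emitter
densities of ordinary dSTORM movies.

## Calibration and the lookup table

`simulate_calibration_scan()` emulates sweeping the focal plane linearly
through a layer of single molecules; with real data any table of
`(z_stage, I1, I2)` works. `build_axial_lut()`:

1. computes $\gamma$ per intensity pair;
2. takes the running median in non-overlapping 25 nm z bins (each bin is
   summarized at its *median z*, not the bin center, so asymmetric sampling
   of a bin does not bias the node);
3. fits the bin medians with a polynomial (default order 7; odd orders track
   the sigmoid trend of $\gamma(z)$ without endpoint oscillation; orders
   3–11 are accepted);
4. samples the polynomial at 1 nm over the largest interval on which it is
   strictly monotone. A scan with no monotone stretch of at least 100 nm is
   a calibration failure, not a usable LUT.

Contrasts outside the tabulated range are rejected at assignment time;
the package never extrapolates the calibration.

```{r calibration}
om <- optical_model() # Gaussian responses at -200/+200 nm, width 300 nm
lut <- build_axial_lut(simulate_calibration_scan(om, noise = "none"))
lut
```

For this default optical model the contrast has the closed form
$\gamma(z) = \tanh\!\big(z\,(c_2-c_1)/(2w^2)\big)$, which the test suite
uses as an independent oracle: the LUT inverts it with a median error far
below 1 nm over the central 80% of its range.

Two conventions are fixed here and documented rather than configurable-by-
accident: the contrast is $(I_2 - I_1)/(I_1 + I_2)$ (the opposite sign
order merely mirrors the calibration curve, so either choice is absorbed by
the LUT), and the transmitted channel supplies the lateral coordinates of a
pair.

## From two channels to 3D localizations

`estimate_channel_transform()` registers the reflected onto the transmitted
channel: a coarse translation from cross-correlating 2D localization
histograms (100 nm bins), control pairs from framewise mutual
nearest-neighbor matching, and a closed-form similarity fit
(translation + rotation + isotropic scale). `pair_localizations()` then
matches the channels frame by frame, greedily in ascending distance with a
500 nm cutoff, so each localization is used at most once; "linear nearest
neighbor" pairing is deterministic with ties broken by record index.
`assign_z()` interpolates $\gamma$ linearly between its bracketing LUT
nodes, and `correct_refractive_index()` applies the single scalar the user
must supply for their immersion/medium combination (default 1.0).

## Fiducial-free drift and tilt correction

A thin membrane layer is its own fiducial. `correct_axial_drift()` tracks
the median z of all localizations in non-overlapping 500-frame windows,
fits the trace with a polynomial in time (default order 6, weighted by
window occupancy) and subtracts it, anchored at the first populated window.
The median is used rather than the mean because protrusion localizations
skew the per-window distribution; on the synthetic membrane model the two
differ by well under 2 nm. `fit_tilt_plane()` renders per-pixel mean z at
100 nm pixels and fits $z = ax + by + c$; `correct_tilt()` removes the
centered plane so the global mean z is preserved. Drift correction must run
before the tilt test: a temporal trend leaks into the plane estimate
otherwise. Both corrections conserve localization counts and leave x, y
untouched.

`estimate_localization_precision()` links localizations in consecutive
frames by mutual 3D nearest neighbors and keeps a track growing while its
cumulative inter-localization distance stays below 75 nm. Per-axis
deviations from each track mean are pooled and a Gaussian is fitted to
their histogram (the RMS deviation is used below 50 pooled deviations,
where a histogram fit is unstable). Deviations are deliberately not
bias-corrected for track length, matching the plain deviation-from-mean
definition; for tracks of length $n$ the expected uncorrected RMS is
$\sigma\sqrt{1 - 1/n}$, so short-track regimes (large $\sigma$ against the
75 nm budget) read a few percent low. The tests assert recovery against
that expectation rather than pretending the estimator is unbiased there.

## Quantifying axial receptor distributions

`render_zstack()` bins corrected localizations at 20 nm laterally and
20 nm in z (half-open bins; a coordinate exactly on an edge belongs to the
upper bin), `tile_rois()` lays non-overlapping 2 × 2 µm squares over a
master mask and keeps those with > 75% mask coverage (clipped to the mask
border), and `axial_profile()` accumulates counts per ROI slice by slice.
The master mask was drawn manually in the original workflow;
`make_master_mask()` offers an automatic stand-in (density threshold,
morphological closing, 1 µm erosion via EBImage), and any logical matrix
can be supplied instead.

Each profile is fitted with a bi-Gaussian,

$$y = a_1 e^{-\frac12\left(\frac{x-m_1}{s_1}\right)^2}
    + a_2 e^{-\frac12\left(\frac{x-m_2}{s_2}\right)^2},$$

by bounded least squares ($a_i \ge 0$, $s_i \in [10, 1000]$ nm, means
inside the profile range — bounds are documented defaults, not claims about
the original fits). Initialization takes the two most prominent local
maxima of the lightly smoothed profile, with a moment-based fallback start;
components are relabeled so $m_1 \le m_2$. When one amplitude converges to
effectively zero (< 0.1% of the other), the vanished component's location
and width are tied to the dominant one: the profile is mono-modal and its
derived parameters should collapse accordingly. Three descriptors follow,
with $\mathrm{FWHM}_i = 2.355\,s_i$:

* z-distribution width
  $z_w = (m_2 + \mathrm{FWHM}_2/2) - (m_1 - \mathrm{FWHM}_1/2)$ — the
  overall axial spread;
* peak-to-peak distance $\text{p-p} = |m_2 - m_1|$ — how separated the two
  populations are;
* width difference $\Delta_\mathrm{FWHM} = |\mathrm{FWHM}_1 -
  \mathrm{FWHM}_2|$ — how much broader the second population is.

By construction $z_w \ge \text{p-p}$ and
$z_w \ge (\mathrm{FWHM}_1 + \mathrm{FWHM}_2)/2$; the tests assert both over
randomized parameter sets.

`fit_population()` pools a parameter over many ROIs, histograms it and fits
the user-chosen model — mono-Gaussian, bi-Gaussian, or mono-exponential
decay (reported by $\tau$, the inverse decay constant). Model choice is
explicit, not automatic: which receptor calls for which model is a
scientific decision. Gaussian components are summarized as
$\mu \pm \mathrm{FWHM}/2$ rounded half-up to integer nm
(`population_range()`); round-half-up, not banker's rounding, is what makes
the published example ranges reproduce exactly from their printed
$(\mu, \sigma)$.

```{r params}
compute_axial_params(data.frame(m1 = 100, s1 = 20, m2 = 180, s2 = 30))
population_range(c(247, 63), c(83, 22))
```

## Image homogeneity (GLCM)

`homogeneity_score()` quantifies how evenly a fluorescence signal covers a
cell contact, used to compare coverslip coatings: 8-bit conversion
(min–max rescale; the source scaling was unstated, so the choice is
documented here), ISODATA background zeroing, gray-level co-occurrence
matrices at unit offset for the four directions 0, π/4, π/2, 3π/4 with the
zero row/column removed and the matrix normalized, entries weighted by
$1/(1+|i-j|)$ and summed, then averaged over directions. The weight's
printed form was ambiguous ("divided by 1 + (i, j)"); the standard
inverse-absolute-difference homogeneity weight is the default and
$1/(1+(i-j)^2)$ is available via `weight = "sq_diff"`. Directions whose
matrix is empty after background removal score 0 instead of aborting, so a
mostly background image still yields a value. The implementation agrees
exactly with a brute-force pair-enumeration oracle in the tests.

## The synthetic-data generator

`simulate_membrane_locs()` emulates what the pipeline needs to be tested
end to end, with full ground truth per appearance:

* a two-level surface (base at 0, protrusion tips at 150 nm — a typical tip
  height above the contact plane — tip radius 50 nm, 2 tips/µm²,
  configurable fraction of emitters on tips, 25 nm axial jitter);
* blinking with geometric on-times (mean 3 frames), no re-activation model;
* per appearance, a photon budget (mean 2000) split between the channels in
  proportion to the two Gaussian axial responses (offsets ∓200 nm, width
  300 nm), optionally Poisson-noised, and independent lateral noise per
  channel. Splitting one budget — rather than giving each channel an
  independent response amplitude — matches a 50/50 beamsplitter, conserves
  photons and leaves $\gamma(z)$ identical, since the ratio cancels the
  common factor;
* optional injected axial drift (any function of frame), a tilt plane, and
  a known lateral offset of the reflected channel to exercise registration.

What the generator does **not** emulate: realistic PSF shape changes with
defocus, fluorophore photophysics beyond geometric on-times, background
autofluorescence, or the cell-to-cell variability of real membranes. Tests
passing on this model therefore validate the *algorithms* (calibration
inversion, pairing, corrections, fitting, bookkeeping), not biological
effect sizes; the published per-receptor population means come from real
cells and are reproduced only qualitatively (tip-clustered scenarios yield
smaller mean $z_w$ and p-p than dispersed ones).

## Numerical choices and degenerate inputs

* LUT nodes at 1 nm make linear interpolation error negligible against the
  photon-noise floor (~10 nm s.d. at 2000 photons).
* Pairing and track linking break distance ties by record index, making
  runs deterministic; reruns of the same inputs are byte-identical.
* Underfilled calibration bins (< 5 pairs) are dropped with a warning; a
  constant-contrast scan, an all-background texture image, a drift trace
  with < 4 populated windows, collinear tilt pixels, and profiles with < 8
  nonzero bins are all hard errors naming the problem.
* Polynomial fits (LUT, drift) are performed in scaled variables
  (z/1000, frame/frame_max) for conditioning; coefficients are stored in
  the scaled basis.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to keep each check well-conditioned: calibration scans
of 81 stage positions × 25 appearances; 1000 noisy appearances per depth
level for the precision claim; 100k localizations over 50k frames for
drift/tilt recovery; ~20k appearances per topography scenario over 25 ROIs;
100 random images against the texture oracle.

## Known limitations

* Lateral drift is out of scope (handled upstream in the original
  workflow); only axial drift is corrected.
* The refractive-index factor is a user-supplied scalar, not estimated.
* The precision estimator's track-length bias (above) is documented, not
  corrected.
* `fit_bigaussian()` on genuinely mono-modal profiles is a degenerate
  problem; the amplitude-collapse rule makes the derived parameters stable,
  but $m_2, s_2$ of a collapsed fit carry no independent information.
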