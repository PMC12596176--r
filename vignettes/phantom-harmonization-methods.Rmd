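---
title: "Methods: simulated chest-phantom analysis for low-dose QCT harmonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated chest-phantom analysis for low-dose QCT harmonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungqct)
```

# The measurement problem

Quantitative CT lung metrics — mean and SD of Hounsfield units in a
region, the coefficient of variation, low-attenuation-area percentages,
and the modulation transfer function — depend on the acquisition and
reconstruction chain, not only on the object. Harmonizing a low-dose
protocol across scanners therefore means scanning a common anthropomorphic
chest phantom with known test inserts under candidate settings and scoring
each candidate against a reference protocol. `lungqct` implements that
analysis chain, together with a synthetic phantom so that every stage can
be validated against exact ground truth.

# The synthetic phantom

## Geometry

The phantom emulates a commercial anthropomorphic chest phantom with
outer chest plates: an elliptic body cross-section of 435 mm (left-right)
by 229 mm (anterior-posterior) of soft-tissue-equivalent material, two
elliptic foam lungs, and three tubular channels running the length of the
chest cavity — one large channel (50 mm bore) in the right lung and two
smaller ones (28 mm bore, anterior and posterior) in the left. Labelled
inserts are stacked along each channel in 40 mm segments. Four
configurations are provided: `"i"`–`"iii"` spread the test objects
(lung-core samples, the MTF cube, air, water vials, acrylic, PMP,
low-contrast epoxy, synthetic bone, standardized foams) over three
series, while `"iv"` packs water, air, the MTF cube and one lung sample
into the large channel so a single series carries all primary inserts.

The physical phantom has no public blueprint, so all placement constants
(tube positions, bores, segment lengths, carrier radii) are package
constants in `phantom_geometry()`; they are chosen to be geometrically
plausible, not claimed to replicate any particular physical unit. The
2 cm resolution cube is tilted by 2 degrees about the z and x axes by
default: physical inserts are never perfectly aligned with the scanner
axes, and the small obliquity is also what gives the edge-based MTF
estimator its sub-pixel phase diversity (see below). The tilt is
*estimated* from the image during analysis, never assumed.

## Materials

Air and water are ground truth at −1000 and 0 HU. Standardized foam and
phantom-foam values are fixed at reference-protocol measurements of the
physical inserts (e.g. 8 lb foam −883 HU, phantom lung foam −629 HU);
plastics use textbook CT numbers (HDPE −80 HU, PMP −180 HU). Lung-core
samples are heterogeneous: they receive a seeded Gaussian field smoothed
with a 1 mm kernel and scaled to a 130 HU texture SD around a −656 HU
mean, so low-attenuation-area fractions are non-trivial and their ground
truth can be computed by brute-force counting on the noiseless volume.

## Scan model

`simulate_scan()` is a linear blur-plus-noise model:

* a separable Gaussian PSF (defaults `psf_sigma_inplane` = 0.5 mm,
  `psf_sigma_z` = 0.54 mm, placing the 50 % cutoffs near 3.7 and 3.5
  cycles/cm, typical of neutral reconstruction kernels), applied as
  truncated, row-renormalized convolution so extended uniform regions
  keep their mean exactly;
* stationary noise obtained by circularly filtering seeded white noise
  with a small 3-D kernel normalized to unit sum of squares (default: a
  mildly positive-correlated 3×3×3 stencil), scaled to
  `noise_sd_at_reference * sqrt(reference_ctdi / ctdi_vol)` — the
  standard quantum-noise relation. Defaults anchor 15 HU of noise at a
  2.22 mGy reference dose.

What the simulator deliberately does **not** model: beam hardening,
scatter, polychromatic spectra, dose-modulation tube-current profiles,
vendor reconstruction algorithms, or respiratory states. The analysis
pipeline, not CT physics, is the artifact under test; the net effect of
acquisition and reconstruction is abstracted into the PSF and noise
parameters. Consequently, passing tests demonstrate correctness of the
*measurement* chain on images whose resolution and noise are controlled —
they do not demonstrate that any physical scanner behaves like the
simulator, and scanner-specific effects (scatter-induced HU bias in
air-like regions, non-Gaussian reconstruction kernels, nonstationary
noise under dose modulation) are outside what the synthetic data can
show.

# Segmentation

Lungs are segmented by thresholding below −300 HU inside the body
(exterior air is removed by filling the body outline slice-wise),
labelling connected components in 3-D, and keeping the two largest.
Insert masks are *model-based*: the layout geometry is aligned to the
image and each insert's cylinder or cube is instantiated directly. The
translation estimate uses

* the centroid of the **filled body outline** for (x, y) — by symmetry
  this is exactly the body centre, and unlike the raw body-mass centroid
  it is not biased by the asymmetric tube and carrier mass, nor corrupted
  when strong blur erodes thin tube walls;
* matching of the measured axial HU profile inside each tube bore against
  the layout's expected payload sequence for z (integer-slice search over
  ±20 mm by default).

Masks are then eroded by a spherical margin (default 1 mm, roughly two
in-plane voxels at the clinical geometry) to exclude walls and
partial-volume voxels. An insert whose measured mean HU deviates from its
nominal value by more than 250 HU — or which falls outside the volume —
is reported as missing while the remaining masks are still returned, so a
series with an unmeasurable insert degrades gracefully. The model-based
masks make region sizes essentially identical across noise levels, which
is the property a harmonization comparison needs.

# Densitometry

`roi_stats()` computes the mean and the sample SD (n−1 denominator; the
choice is immaterial at these region sizes but must be fixed for the
oracle tests). The CoV is SD divided by the **absolute** mean — air has a
negative mean but is reported with a positive CoV — and defined as 0 for
an exactly zero mean. LAA percentages use strict `<` comparisons at
−950 and −856 HU. Published tables round before printing: dividing the
printed water statistics 26.2/3.8 gives 6.89 where 6.87 was printed from
unrounded inputs; the package always computes from full precision and the
tests assert agreement within 0.05.

# Resolution: cube-edge MTF

The estimator follows the edge-spread route: for one exposed face
perpendicular to each axis, rays are cast through voxel centres across
the central region of the face (margin 25 % of the half-edge from the
cube edges); each ray's edge position is the half-height crossing,
located by local cubic interpolation (a two-point chord carries a
curvature-dependent sub-voxel bias); a plane fitted through the per-ray
edge positions provides sub-voxel alignment and, through its obliquity,
the cosine distance correction for the near-axis-aligned face. All
samples are projected onto their signed distance from the fitted plane
and averaged in bins of one tenth of the voxel pitch, with each bin's
knot placed at the mean sample position inside it (placing knots at bin
centres would quantize the edge by up to half a bin). Because the face is
slightly oblique to the grid, the per-ray phases tile the voxel pitch and
the binned ESF is genuinely super-sampled — this is what makes cutoff
recovery accurate well beyond the native sampling rate.

The LSF is the finite difference of the ESF. The window applied before
the FFT deserves a note: its purpose is to remove noise in the LSF tails,
but a Hann window spanning the whole profile also narrows wide LSFs and
biases the cutoffs upward (measurably so for PSF sigma above about 1 mm
at this profile length). The package therefore uses a tapered window —
flat over the core, Hann-shaped tails — centred on the aligned edge, with
a half-width adapting to the measured 10–90 % edge rise (4 × the
Gaussian-equivalent FWHM, clamped to the profile). Both the taper
fraction and the width multiplier are exposed (`taper`, `fwhm_mult`).
The modulus of the zero-padded FFT, normalized at zero frequency, gives
the MTF; cutoffs are the first downward crossings of the 50 % and 20 %
levels by linear interpolation, in cycles/cm. The in-plane curve is the
pointwise mean of the x and y curves on a common frequency grid, with
cutoffs recomputed on the averaged curve (the alternative — averaging
cutoffs — differs only when the two curves disagree, in which case the
averaged-curve convention is the better-defined one).

Validation is analytic: `render_gaussian_cube()` renders the exact
continuous Gaussian blur of a tilted cube sampled at voxel centres, for
which `f50 = sqrt(ln 2 / (2 π² σ²))` and
`f20 = sqrt(ln 5 / (2 π² σ²))` in closed form. The test suite requires
2 % cutoff recovery noiselessly and 5 % under 15 HU white noise with 49
rays, for sigma from 0.3 to 1.2 mm on the clinical 0.51/0.5 mm grid.
Exact agreement with any physical scanner's published MTF values is not
claimed — that would require the original raw images; the estimator's
own parameters (ray count, resampling pitch, window) are stated here
precisely because no publication of the physical workflow states theirs.

# Noise power spectra

The in-plane NPS tiles non-overlapping square patches (default 64×64)
over a uniform region, detrends each patch with a 2-D polynomial
(default order 2), and averages `|FFT|² · (px·py)/(Nx·Ny)` over patches
and slices before radial binning (bin width = one DFT bin). With this
normalization the integral of the 2-D NPS over the frequency plane equals
the detrended voxel variance (Parseval), which the tests assert within
5 %. The z-direction NPS does the same per (x, y) column along ≥ 32
contiguous slices. Note that polynomial detrending *deliberately*
suppresses the lowest-frequency bins; shape comparisons against a known
filter transfer are therefore made with mean-only detrending and the DC
bin excluded, while variance conservation is asserted at the default
order. `nps_peak()` reports the frequency of maximum power with parabolic
sub-bin refinement and flags white-like spectra as flat when the maximum
is within 1.5× the median.

# Dose arithmetic and the selection rule

Effective dose is `CTDIvol (mGy) × scan length (cm) × k` with the chest
conversion factor k = 0.027 mSv/(mGy·cm) and a 30 cm scan length; full
precision is kept internally and displayed at 2 decimals with
half-away-from-zero rounding (base R's round-half-even would print 2.84
where harmonization reports print 2.85). Recomputing a published
12-protocol dose table reproduces 10 of 12 printed values exactly; the
two exceptions differ by one display unit and are asserted as known
rounding inconsistencies of the source table, not matched.

`select_protocol()` formalizes the two-stage rule. Stage 1 scores each
candidate by the summed absolute mean-HU difference from the reference
over the primary inserts (air and both water vials — the materials with
known ground truth) and by an MTF summary (mean of the available
cutoffs). A candidate that uniquely minimizes the HU difference — no
other candidate within `hu_tie_tol` — and sits within `mtf_tie_tol` of
the best MTF is selected outright. Otherwise stage 2 selects, among the
HU-tied candidates, the one with the lowest summed HU SD. The tolerances
are explicit parameters (defaults 5 HU and 0.1 cycles/cm; the published
workflow states no numeric thresholds, and 0.1 cycles/cm is the margin
its own prose uses when calling MTFs equivalent). Final ties fall back to
alphabetical candidate id so the selection is order-invariant; the full
audit trail of scores and comparisons is returned.

# Problem sizes and numerical choices

Tests and the acceptance script simulate the full phantom at
1.5 × 1.5 × 2 mm voxels (about 4–5 M voxels per volume), which keeps a
complete rasterize–simulate–segment cycle at a few seconds while leaving
every insert tens of voxels across. Resolution measurements always use
the clinical 0.51 × 0.51 × 0.5 mm geometry, either on analytic cube
renderings (120³ voxels) or on a fine sub-grid rasterized around the
large tube (`rasterize(..., require_all = FALSE)`). These sizes are the
package's own validation choices; all analysis code is
resolution-agnostic.

Other fixed numerical conventions: voxel indices are 1-based in R with
world coordinates in mm at voxel centres; the DICOM writer stores
unsigned 16-bit pixels with Rescale Slope 1 / Intercept −1024; slice
interval is derived from inter-slice positions rather than the thickness
tag (overlapping reconstructions make the two differ); erosion uses
integer-voxel spherical offsets, so margins smaller than one voxel erode
nothing; rasterization is deterministic given the texture seed and
seed-independent for untextured materials; all simulated noise is
reproducible from integer seeds.

# Known limitations

* The simulator's linear shift-invariant model cannot represent
  nonstationary dose-modulated noise or nonlinear (iterative/deep
  learning) reconstruction behaviour; candidates differing only in such
  properties are outside its reach.
* Segmentation assumes the scanned configuration matches the declared
  layout and recovers translation only; physical rotations of the phantom
  are not modelled (iso-centred, consistently oriented positioning is the
  use case).
* The DICOM support is intentionally minimal (uncompressed Explicit VR
  Little Endian, single-frame CT); it is not a conformance
  implementation.
* MTF cutoffs beyond roughly the native Nyquist band rely on the edge's
  phase diversity; a face exactly aligned with the grid limits recovery
  to the native band.
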