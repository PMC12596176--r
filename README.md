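# lungqct

Quantitative CT (QCT) lung imaging is used as an endpoint in multi-center
studies of COPD and asthma, which makes the acquisition protocol part of
the measurement: the same lungs must yield the same Hounsfield-unit (HU)
statistics on every scanner. `lungqct` implements the phantom-based
analysis chain used to *harmonize* low-dose chest protocols across
scanners — the workflow in which an anthropomorphic chest phantom with
known test inserts (air, water, standardized foams, fixed lung-core
samples, a 2 cm resolution cube) is scanned under candidate
dose-modulation / iterative-reconstruction settings and each candidate is
scored against a reference protocol.

The package provides, for people doing CT protocol QA and harmonization:

* **Phantom simulation** — a chest-phantom generator (elliptic body
  435 × 229 mm, two foam lungs, three tubular channels with labelled
  inserts in four configurations) rasterized into ground-truth HU volumes,
  plus a linear scan simulator with a separable Gaussian PSF and
  dose-dependent correlated noise following the quantum-noise relation
  `SD ∝ CTDIvol^(-1/2)`.
* **Volume I/O** — NIfTI (via RNifti) and a minimal uncompressed DICOM
  series reader/writer with mandatory HU rescale calibration.
* **Automated segmentation** — lungs by threshold + connected components;
  inserts by aligning the expected layout (filled-body centroid in-plane,
  axial tube-profile matching) and instantiating eroded geometric masks.
* **Densitometry** — per-insert mean/SD, coefficient of variation
  (CoV = SD / |mean|), low-attenuation areas LAA-950 and LAA-856 (percent
  of voxels strictly below −950 / −856 HU), and difference tables against
  a reference protocol.
* **Resolution** — the modulation transfer function (MTF) from the cube
  insert: per-ray edge-spread functions across each exposed face, aligned
  sub-voxel on the fitted edge plane, averaged, differentiated to the line
  spread function, windowed and Fourier-transformed; reported as in-plane
  (mean of x and y) and z-direction curves with the 50 % and 20 % cutoffs
  `f50`, `f20` in cycles/cm. For a Gaussian PSF,
  `f50 = sqrt(ln 2 / (2 π² σ²))`, the closed form the estimator is
  validated against.
* **Noise power spectra** — in-plane (radially averaged, patch-based) and
  z-direction NPS with a variance-conserving normalization
  (∫ NPS df = detrended voxel variance).
* **Dose arithmetic and protocol selection** — effective dose
  `mSv = CTDIvol × 30 cm × 0.027`, percent dose reductions, and the
  two-stage selection rule: minimize the absolute mean-HU difference from
  the reference over the primary inserts (air, two water vials) while
  maximizing the MTF; when candidates tie, take the lowest summed HU SD.

## Worked example

```r
library(lungqct)

## candidate metric sets from a harmonization session: four
## dose/reconstruction combinations on one scanner vs the reference
ex  <- load_example_harmonization()
sel <- select_protocol(ex$candidates, ex$reference)
sel$selected
#> [1] "drive_admire5_3.43"
sel$stage
#> [1] "sd_tiebreak"
sel$audit
#>                   id  dhu   mtf sd_sum hu_tied mtf_preferred selected
#> 1 drive_admire3_2.40 35.1 4.430   96.3   FALSE         FALSE    FALSE
#> 3 drive_admire3_3.43 24.4 4.490   84.4    TRUE         FALSE    FALSE
#> 2 drive_admire5_2.40 32.4 4.570   68.2   FALSE          TRUE    FALSE
#> 4 drive_admire5_3.43 22.8 4.635   58.7    TRUE          TRUE     TRUE
```

The strongest iterative-reconstruction setting at the higher candidate
dose wins: two candidates tie on the HU difference (`dhu`, summed over
air and both water vials, within the 5 HU tolerance), so the rule falls
through to the noise tie-break and picks the candidate with the smallest
summed HU SD (58.7 HU).

Dose arithmetic on the bundled protocol table:

```r
d <- load_protocol_doses()
format_msv(2.22)                                  # reference low-dose
#> [1] "1.80"
s <- summarize_reductions(percent_reduction(7.32, d$ctdi_vol[d$group == "low"]))
round_half_up(unlist(s))
#> mean   sd  min  max
#>   54    7   42   70
```

Simulation and measurement end to end:

```r
lay  <- build_layout("iv")                        # water, air, cube, lung sample
rt   <- rasterize(lay, c(1.5, 1.5, 2), c(300, 160, 88))
scan <- simulate_scan(rt$volume, acquisition_model(ctdi_vol = 2.22, seed = 1))
m    <- segment_inserts(scan, lay, margin = 2)
roi_stats_table(scan, m)[, c("label", "mean_hu", "sd_hu")]
## air recovers about -1000 HU and water about 0 HU at ~15 HU noise
```

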