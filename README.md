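# solls

Simulation and analysis of **single-objective lattice light sheets
(soLLS)** — thin excitation sheets launched and detected through one
high-NA objective, shaped by a slit photomask at the back focal plane and
redirected into the sample by a reflective micromirror. The package is
aimed at microscope builders and analysts who want to reason about such
sheets quantitatively without hardware: how far a lattice sheet of a given
focal thickness stays thin, how it survives scattering compared with a
Gaussian sheet, and what that buys in single-molecule imaging.

It provides, in plain R:

* a scalar Fourier-optics engine — angular-spectrum propagation
  `exp(i d sqrt(k²n² − kx² − ky²))`, ideal-lens `2f` Fourier mapping
  `u = x/(λf)`, and 3D volume synthesis;
* beam construction — slit-photomask lattice sheets (auto-scaled to a
  target waist), cylindrical-lens Gaussian sheets, sinusoidal dithering,
  calibrated galvo/tunable-lens steering, and micromirror reflection;
* beam metrics — 1/e² thickness curves `w(x)` and the **effective range**,
  the span over which `w(x) ≤ √2 · w0` (the light-sheet analogue of the
  Gaussian confocal parameter `2πnw0²/λ`);
* a split-step scattering simulator (random phase screens, absorbing
  obstacles) for self-healing comparisons;
* a synthetic single-molecule movie generator with Gaussian and
  double-helix PSFs and a full EMCCD noise chain (Poisson → Gamma EM
  register → read noise → A/D);
* the localization pipeline: wavelet detection, weighted least-squares
  Gaussian fitting, EMCCD localization precision, double-helix z fitting,
  fiducial drift correction, threshold filtering, 0.75× axial rescaling,
  region statistics, SBR, and FRC resolution at an 8 nm render pixel.

## Worked example

Build a matched-waist pair of sheets (1.8 µm 1/e² focal thickness, 560 nm,
water) and compare their effective ranges:

```r
library(solls)

train <- optical_train()                 # NA 1.45, f = 1.8 mm, n = 1.33
lattice  <- make_lattice_sheet(mask_spec(), train)   # 3 slits, auto-scaled
gaussian <- make_gaussian_sheet(sheet_spec("gaussian"), train)

ls_metrics(lattice)
#> <ls_metrics> waist 1.479 um at x = 51.00 um, width 33.30 um, effective range 120.00 um (symmetric)
ls_metrics(gaussian)
#> <ls_metrics> waist 1.800 um at x = 0.00 um, width 32.90 um, effective range 48.25 um (symmetric)
```

The Gaussian sheet's range reproduces its confocal parameter
(`2π·1.33·1.8²/0.56 = 48.3 µm`); the ideal lattice sheet stays within the
√2 band across the whole ±60 µm synthesis span (its fitted central-lobe
radius oscillates Talbot-like and even dips below the focal value, which is
why its waist sits off-focus), giving a range ratio of **2.49** — the
measured improvement of the real instrument, 1.5-fold, is a lower bound of
this ideal-optics number. A full simulate–image–localize–analyze run is one
call:

```r
res <- run_pipeline(default_run_config(), out_dir = "demo_run")
res$report$median_photons            # 4296
res$report$median_uncertainty_xy_nm  # 5.03
```

which writes `beam.tif`, `movie.tif`, `locs.csv`, `report.yaml` and the
resolved `config.yaml` into `demo_run/`.

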