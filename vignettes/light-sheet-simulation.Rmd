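---
title: "Models and methods behind solls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind solls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`solls` simulates single-objective lattice and Gaussian light sheets at the
desk and re-implements the quantification and single-molecule analysis used
to characterize them. This vignette records the models, the parameters that
matter, and the design decisions made where the design was genuinely open,
so that every number the package produces can be traced to an explicit
assumption.

## Scalar Fourier-optics model

All beam simulation is scalar diffraction on regular 2D grids
(`scalar_field`). Free-space transport uses the exact (non-paraxial)
angular-spectrum kernel `exp(i d sqrt(k^2 n^2 - kx^2 - ky^2))`; evanescent
components are set to zero rather than exponentially decayed, because every
propagation distance of interest here is thousands of wavelengths.
Polarization is out of scope: the real instrument uses circularly polarized
excitation and an NA 1.45 objective, for which a vectorial (Richards-Wolf)
treatment would modify the finest focal structure. The scalar choice is a
documented limitation, adequate for the sheet-scale quantities (thickness,
range, robustness orderings) the package targets.

Two numerical safeguards apply to `propagate_angular_spectrum()`:

* zero padding (factor 2 by default) before the spectral multiply, to
  suppress periodic wrap-around of compact fields; strictly periodic fields
  (plane waves) should be propagated with `pad = 1`;
* an aliasing guard that errors when more than 0.1% of spectral power sits
  in the outer 10% of the grid's Nyquist band.

The ideal lens (`lens_fourier()`) maps its front focal plane to the back
focal plane as a scaled Fourier transform, `u = x / (lambda f)`, normalized
so that Parseval power equality is exact and two applications reproduce the
input spatially inverted. `synthesize_volume()` assembles 3D intensity
volumes (one FFT per plane after a precomputed spectrum) with the axis
convention x = propagation, y = sheet width, z = sheet thickness.

## Building the sheets

**Lattice sheet.** The pupil amplitude is a binary slit photomask: by
default three equally spaced slits (centers -1.2, 0, +1.2 mm; outer
separation 2.4 mm; width 0.08 mm) in a substrate of optical density 5.2
(amplitude `10^(-OD/2)` outside the slits). The exact slit count of the
physical pattern is not public; three slits are the minimal symmetric
multi-Bessel sampling consistent with an "outer slits" geometry, and the
count is configurable. Slit edges are sampled with sub-pixel coverage so
that mask geometry varies smoothly under rescaling.

Two free parameters of the physical train are not derivable from public
information and are handled explicitly:

* *Objective focal length*: 1.8 mm by default (180 mm tube standard divided
  by the 100x magnification), configurable in `optical_train()`.
* *Relay magnification between mask and pupil*: unknown, so
  `make_lattice_sheet()` auto-scales all mask coordinates by one factor,
  found by root search, such that the fitted 1/e^2 focal thickness of the
  central lobe equals the requested waist (1.8 um by default). The
  Gaussian-equivalent search window is scale 0.02-1, and the synthesized
  volume is verified to be within 5% of the target.

The illuminating laser spot is modeled as a Gaussian envelope sized to the
slit pattern (twice the outer pattern extent along the slit axis, and along
the slit length an envelope whose Fourier transform gives the requested
sheet width, 32.9 um 1/e^2 by default). Sizing the illumination with the
pattern keeps the finite-OD leakage proportionate to the open area; an
unbounded uniform illumination would integrate OD leakage over the whole
grid and, at small mask scales, bury the lattice under the leaked
background, which is not how a real system is aligned.

**Gaussian sheet.** The cylindrical-lens sheet is constructed directly in
the focal plane: Gaussian in z with the requested 1/e^2 waist, and an
order-8 super-Gaussian flat-top along y with 1/e^2 half-width equal to the
sheet width. Its synthesized effective range reproduces the confocal
parameter `2 pi n w0^2 / lambda` within the fit tolerance, which doubles as
an end-to-end oracle for the propagation engine.

**Dither.** Sinusoidal scanning along y is emulated as a time average over
one period of `A sin(2 pi t)` at 32 uniform time samples, using periodic
linear-interpolation shifts (so per-plane energy is conserved exactly).
Averaging under the arcsine dwell attenuates a periodic ripple of period p
by `|J0(2 pi A / p)|`; the tests assert this law against a dense-quadrature
oracle. Note that this attenuation is not monotone in A, and a single-period
dither amplitude only suppresses ripple completely at the Bessel zeros
(A ~ 0.38 p, ...); the instrument's shadow-removal dither operates in the
large-A regime. The default amplitude, 3.5 um, corresponds to a 0.1 V sine
on a galvo calibrated at 35 um/V.

**Steering and mirror.** Steering is strictly linear with the calibrated
slopes 0.64 um per 0.01 V (axial), 0.35 um per 0.01 V (in-plane) and
2.41 um per 10 mA (focus). The Gaussian path lacks the lattice path's
beam-shrinking relay; its galvo response is doubled via a per-family
multiplier (the factor is applied to the Gaussian path, the natural reading
of a "2x difference" caused by an extra telescope in the lattice path; the
multiplier is configurable if the opposite assignment is wanted). The
micromirror reflection is a rigid rotation of the volume by
`2 * (45 - wall angle)` degrees (12 degrees downward for the 39-degree
insert), implemented with the three-shear decomposition using periodic
fractional shifts, which conserves total intensity exactly; no
re-diffraction at the mirror is modeled, since the mirror is flat and large
relative to the beam.

## Quantifying the sheets

Thickness is the 1/e^2 intensity radius of a least-squares Gaussian fit to
the z-profile at the sheet's y-center, per x-plane. For lattice profiles
the fit is restricted to the central lobe (between the first flanking local
minima); side lobes would otherwise bias a global Gaussian fit. The
*effective range* is the longest contiguous x-interval containing the waist
over which the fitted thickness stays within sqrt(2) of the waist value,
with sub-sample crossings located by linear interpolation. The sqrt(2)
criterion is applied to 1/e^2 radii, not FWHM, matching the convention used
for every other width in the package. A `post_focus` mode measures from the
waist forward only, for situations where the pre-focus region is not
accessible to measurement; for an ideal symmetric beam it returns half the
symmetric range.

Two behaviors of the ideal simulation deserve note. First, a three-slit
lattice evolves Talbot-like along x: the fitted central-lobe radius
oscillates slowly and can dip *below* its focal value away from the focus,
so the curve minimum (the waist used by the criterion) need not sit at
x = 0. Second, over the default +/- 60 um synthesis span the ideal lattice
never leaves the sqrt(2) band, so its effective range is the span itself
and the reported lattice/Gaussian ratio is a lower bound tied to that span.
Real measured ranges are shorter on both arms (aberrations, scattering, and
measurement windows an ideal simulation does not contain), which is why the
package targets the *ratio*, not the absolute ranges.

## Scattering medium

The agarose/bead/dye experiment is emulated qualitatively: thin random
phase screens with Gaussian autocorrelation (spectral filtering of white
noise; two parameters, per-screen RMS phase and correlation length) at
regular spacings, optional absorbing scatterers (Poisson positions, applied
as opaque disks at the nearest screen) and deterministic obstacles. No
quantitative scattering coefficient is derivable from the public recipe, so
the defaults (RMS 0.6 rad per screen every 5 um, correlation length 2 um)
are chosen once so that a Gaussian sheet visibly degrades within tens of
micrometres; nothing in the package treats them as a calibration. The
self-healing comparison runs matched-waist lattice and Gaussian sheets
through the *identical* medium realization with a strip obstacle blocking
the beam core at focus and compares each beam's correlation with its own
unobstructed profile 10 um downstream.

## Synthetic single-molecule movies

Blinking is per-frame independent Bernoulli (PAINT-like); binding-duration
kinetics are deliberately omitted at 100-200 ms exposures. Excitation
weight is the normalized illumination intensity interpolated at the
emitter's 3D position (1 everywhere for epi). The Gaussian PSF widens with
defocus as `sigma0 sqrt(1 + (z/z_d)^2)` with `z_d = 0.4 um`, which is what
makes out-of-plane emitters contribute diffuse background under epi
illumination. The double-helix PSF is two equal Gaussian lobes separated by
1 um whose axis rotates at 90 deg/um over +/- 1 um (short range; 30 deg/um
over +/- 3 um for the long-range fiducial channel). The commercial phase
masks' true parameters are not public; these are configurable placeholders,
and every z-related test round-trips through the same model rather than
asserting absolute mask properties.

The camera chain is: Poisson shot noise on expected photons, electron
multiplication as Gamma(shape = n, scale = em_gain) — the standard cascade
approximation whose excess noise factor tends to 2 — Gaussian read noise in
electrons, then A/D conversion at 4.41 photoelectrons per count on top of a
500-count dark level, with the calibrated 157 x 159 nm pixels and EM gain
182. Dye background is proportional to the z-integrated normalized
illumination, so a sheet suppresses it relative to epi by its confinement
ratio.

## Localization pipeline

Detection is an undecimated B-spline (order 3) wavelet transform; spots are
8-connected local maxima of the second wavelet level above twice the
standard deviation of the first (noise) level. Fitting is weighted least
squares of a pixel-integrated symmetric Gaussian plus constant background,
with weights from the expected per-pixel EMCCD variance
(`2 mu + (read/gain)^2` photons^2), re-weighted once. Double-helix spots
are fit as two equal lobes with fixed separation; depth follows from the
lobe angle wrapped into (-90, 90], which resolves the lobe-exchange
degeneracy.

The EMCCD localization precision is the least-squares expression

```
sigma_loc^2 = (sa^2 / N) * (F * 16/9 + 8 pi sa^2 F b / (N a^2)),  F = 2
```

with `sa^2 = sigma^2 + a^2/12`. The citation chain for the exact algebra is
not public, so the package treats the Monte-Carlo fitting ensemble as the
authoritative contract: the formula is required (and tested) to agree with
the empirical scatter of the weighted fit at the reference operating point
(4320 signal photons, 16.1 background photons per pixel) within 25%.

Drift correction subtracts the per-frame mean fiducial displacement,
linearly interpolated over gaps and smoothed with a centered 50-frame
moving average; the exact algorithm behind the original instrument's
correction is unspecified, and this mean-subtraction contract is the
package's own. Filtering applies named threshold rules (uncertainty and
photon-count bounds) and logs removals per rule; axial coordinates are then
rescaled by 0.75 for the glass/water index mismatch. Region statistics bin
the field of view into five equal-area rectangles along x (region 1 at the
reference/mirror edge) and report counts, counts normalized to region 1,
and mean +/- sd of SBR and uncertainty — means and standard deviations
only, no hypothesis tests, matching how such comparisons are reported.

FRC resolution renders two random halves of the localizations at an 8 nm
super-resolution pixel and takes the first crossing of the ring-averaged
Fourier correlation below the fixed 1/7 threshold (the commercial
implementation's split and threshold conventions are unknown; 1/7 is the
field's standard). The estimate is floored at twice the render pixel.

## Problem sizes and determinism

Default problem sizes are chosen so a full characterization runs in
seconds-to-minutes on one core: back-focal-plane grids of 4096 x 64 for the
lattice (2 um pitch in the slit direction), 512 x 64 focal grids for the
Gaussian sheet, 121 propagation planes over +/- 60 um, movies of tens of
frames at 48-64 pixels square, and Monte-Carlo ensembles of 100-200 fits.
All stochastic stages take explicit seeds and restore the caller's RNG
state; identical configuration and seed reproduce outputs bitwise.

## Known limitations

* Scalar, aberration-free optics; no vectorial focusing, no immersion
  interface Fresnel effects, no detection-PSF deconvolution of beam
  profiles.
* The scattering medium is a qualitative emulation, not a calibrated model
  of any gel; absolute localization-count contrasts in scattering media are
  therefore out of reach by design, and only ordering properties are
  claimed.
* Double-helix parameters are placeholders for unpublished commercial
  masks.
* Blinking has no temporal correlation; multi-emitter (overlapping) fitting
  is not implemented.
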