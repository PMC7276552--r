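---
title: "Inferring colony self-organization from structural colour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring colony self-organization from structural colour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocolony)
```

Colonies of certain gliding, rod-shaped bacteria (the model system is
*Flavobacterium* IR1) pack into polycrystalline lattices whose period —
roughly 400 nm between neighbouring cells — is comparable to optical
wavelengths. The colony therefore behaves as a low-contrast 2D photonic
crystal in cross-section and shows vivid, angle-dependent colour. Because
electron microscopy of such colonies suffers from preparation artefacts
(dehydration shrinks the lattice by tens of percent), the optical response
itself is the most reliable structural probe: diffraction-spot positions
encode the lattice constant, the dispersion of the specular reflection
encodes the average refractive index, and the disorder-induced degradation
of the reflectance peaks encodes how well-ordered the packing is.
`photocolony` implements both directions of this analysis — inverse fits on
angle-resolved scattering data, and forward photonic models of the packed
colony — together with synthetic-data generators that make every stage
testable against known ground truth.

## Angle conventions

All angles are measured from the sample normal. The illumination arm sits
at negative angles, so for incidence `theta_in` the specular direction is
`-theta_in`. A band of about ±5° around `theta_in` carries no signal (the
detector arm occludes the source); those map cells are stored as `NA`.

## Inverse analysis of goniometry data

### Lattice constant from the grating equation

A row of cells spaced `d` apart diffracts like a grating:
`theta_m = asin(m * lambda / d - sin(theta_i))`. `fit_grating()` inverts
detected spot positions jointly over several incidence angles. Orders are
assigned by consensus over the single-peak closed-form inversions
`d = m * lambda / (sin theta_out + sin theta_in)`, the period is then
obtained from the exact sin-space regression through the origin and refined
by angular least squares with a continuous evanescent penalty. On noiseless
synthetic maps the recovery is exact to machine precision; with 0.5°
angular noise over ten seeds the mean recovered period lands within a
couple of nanometres of truth — far tighter than the ±5 nm reproducibility
of the measurement this emulates.

```{r grating, eval = FALSE}
model <- colony_model(d = 395, tilt = tilt_distribution(0, 0, 0))
maps <- lapply(c(0, -45, -60), function(t) synth_goniometer_map(model, t))
fit_grating(maps)
#> <grating_fit> d = 395.00 +/- 0.00 nm (orders -2,-1,1, 8 peaks, ...)
```

Peak detection (`detect_diffraction_peaks()`) refines the angular position
of each spot by a log-parabola — exact for the Gaussian spot kernels of the
forward model — while keeping the wavelength on-grid: moving the wavelength
off-grid would move the point off the grating curve, which is the object
the period fit consumes.

### Average refractive index from the specular dispersion

The specular peak shifts with angle as
`lambda_s = lambda_p * cos(asin(sin(theta_in) / n_avg))`, where `n_avg` is
the volume-average index of cells plus matrix. `fit_specular()` reads
`lambda_p` off the 0° crossing (local quadratic) and fits `n_avg` by 1D
least squares. A trace that is flat to within the noise carries no
information about the index; the fit then returns the search bound with
`lower_bound_flag = TRUE` rather than a spurious estimate.

### Domain tilts and the diffraction streak

Most crystalline domains lie flat on the agar, with a ±10° spread; a
minority is tilted much more strongly. A domain tilted by `alpha` sees an
effective incidence `beta = theta_in - alpha` and its diffracted directions
are rotated back by `alpha`. Its diffraction resonance also shifts: at
normal effective incidence the first-order peak sits near `0.85 d`
(≈336 nm for the day-2 lattice) while obliquely lit domains resonate in the
green (~500 nm at 60°). The generator models this with the monotone
dispersion `lambda_res(beta) = lambda_d / cos(1.25 * asin(sin beta /
n_avg))`, anchored at those two observations. The locus of spots over all
tilts is then *exactly* invariant under the correction
`theta_out_corrected = theta_out - theta_in`, which is what
`extract_and_correct_streak()` applies and what the overlay test checks:
streaks extracted from maps at 0°, −45° and −60° incidence collapse onto a
single curve (RMS below 2°), and flipping the correction sign destroys the
overlay. The corrected-angle window used for the comparison
(`streak_overlay_rms()`) selects one branch of the streak; the default
negative arm is the branch inside the tilt support of all three incidence
angles for the core-plus-tail tilt model, while the uniform-tilt
validation uses the positive arm.

## Forward models

### Effective-index multilayer (transfer matrix)

`stack_from_lattice()` collapses the 2D lattice into a 1D stack: one period
is the row spacing along the propagation direction (`sqrt(3) d / 2` at
normal incidence), discretized into slabs whose index is the area-weighted
chord coverage of the staggered disk rows (8 slabs per period by default;
the slab-average permittivity equals the lattice filling fraction exactly,
so the coarse two-slab variant conserves the optical thickness).
`tmm_reflectance()` is the standard characteristic-matrix recursion;
energy is conserved to machine precision and a 41-period stack peaks at
the m = 2 and m = 3 Bragg wavelengths `2 n_bar Lambda / m` ≈ 471 and
314 nm — the same features the full solvers produce.

### Plane-wave-expansion band structure

`compute_bands()` solves the 2D hexagonal crystal (touching disks,
`n` = 1.38/1.34) by plane-wave expansion: for TM the generalized problem is
symmetrized with the inverse square root of the Fourier permittivity
matrix; for TE the inverse-matrix rule is used. A plane wave at normal
incidence only excites modes that are even under the mirror containing the
propagation direction, so the solver block-diagonalizes into the even and
odd sectors of that mirror. This gives exact symmetry labels — the
field-overlap classifier (`classify_symmetry()`) agrees with them but is
unreliable exactly where it matters most, at nearly degenerate pairs whose
splitting *is* the gap. At a cutoff of 9 (≈313 plane waves) every reported
gap is converged to well below 0.1 nm.

Two kinds of partial gap are reported by `find_partial_gaps()`:

* *full*: wavelength intervals covered by no symmetric band anywhere on
  the leg — the visible gap at 471.6 nm on the ΓK leg and the 336.0 nm gap
  on the ΓM leg are of this kind;
* *local*: avoided-crossing gaps at the k-point of minimal separation of
  two adjacent symmetric bands, valid only if both bands have their
  extremum there and no other symmetric band intrudes nearby. The near-UV
  gap (~308.8 nm) at the ΓK zone corner is of this kind: elsewhere on the
  leg other symmetric bands cover the same frequencies, so it does not
  appear as a full-leg interval.

At the zone corner a cluster of three nearly degenerate symmetric bands
produces stacked sub-nanometre gaps; the validation step retains only the
genuine band-edge gap (both bounding bands extremal at the corner), whose
width of ~0.5 nm is consistent with the sub-nanometre widths expected at
this refractive-index contrast.

A note on direction labels: with lattice vectors `a1 = (d, 0)`,
`a2 = (d/2, sqrt(3) d/2)`, the leg labelled `GK` runs to the zone corner
along the bond direction and carries the two specular gaps (471.6 and
308.8 nm), the leg labelled `GM` to the edge midpoint (336.0 nm gap).
The real-space propagation direction at normal incidence on the colony
surface is perpendicular to the close-packed rows; its Bloch leg in this
basis is the `GM` leg, whose gap set (470.9, 336.0, 313.9 nm) indeed
matches the FDTD normal-incidence peaks below. Band-diagram labels follow
the reciprocal-space convention of bandgap studies of this crystal; the
FDTD orientation labels follow the real-space convention (`"KG"` = normal
incidence, rows parallel to the surface). The two conventions name
different objects, which is why both sets of numbers are quoted.

### 2D FDTD

`run_fdtd()` drives a compiled TM Yee solver (Rcpp): periodic lateral
boundaries, CPML along the propagation axis, a soft line source launching
a broadband differentiated-Gaussian pulse, and running DFTs at two monitor
lines. Reflectance is normalized by a matched reference run on the empty
background (cached per session); the air–sample interface is deliberately
not included — the background is the matrix index everywhere outside the
disks, so the spectra isolate the lattice response. The scattered field at
the reflection monitor is split into lateral Fourier orders: order zero is
the specular channel, the remaining propagating orders the diffracted
channel; the split resums to the total within 1%.

For the perfect lattice (diameter 375 nm, spacing 395 nm, filling fraction
0.6 of a 5 × 5 µm sample) at normal incidence the solver reproduces the
expected structure: strong total-reflectance peaks at ≈470 and ≈336 nm and
a weak ≈312 nm feature, with the long- and short-wavelength peaks carried
by the specular channel and the 336 nm peak almost entirely (>95%) by
first-order diffraction. Rotating the crystal by 30° produces a
qualitatively different multi-peaked visible spectrum, which is how the
crystal orientation relative to the colony surface is identified. Numerical
choices: Courant factor 0.5, grid 10 nm (sub-pixel area-fraction averaging
of boundary cells keeps staircasing peak shifts below ~3 nm against a 5 nm
grid), 16384 steps (energy balance |R+T−1| within the 2% numerical
allowance; runs that violate it abort with diagnostics rather than return
biased spectra).

## Disorder generation and the disorder study

`make_hexagonal()` fills a centred slab of the box so the overall area
fraction is `ff`; with the reference 5 × 5 µm box and `ff = 0.6` this is
136 disks, the constant-count convention that makes ordered and disordered
samples comparable. Disorder is specified by `sigma_k` (relative radial
broadening of the first-shell Bragg peak) and `sigma_phi` (azimuthal
broadening in degrees; `Inf` = isotropic ring).

`generate_disordered()` realizes a specification in two stages. First, a
disorder-matched initial configuration: cumulative row-stacking noise of
`sigma_k * d` per row (paracrystalline, the kind of positional disorder
that actually broadens Bragg peaks, unlike independent site jitter which
only attenuates them — `jitter_lattice()` provides that fast
Debye–Waller-type alternative), and independent rotations of ~650 nm
grains drawn from `N(0, sigma_phi)` (misaligned grains both detune the
Bragg condition and cut the coherent stack). Second, quasi-greedy
simulated-annealing refinement of single-particle moves (step `a/10`, hard
disks never violated) against a target structure factor on a first-shell
polar grid. The default target (`target_sq_empirical()`) is the *measured*
S(q) of the perfect finite packing convolved with the requested widths, so
the zero-disorder limit is exactly attainable; the analytic Gaussian-peak
target (`target_sq()`) is also available. A hot annealing start, or an
analytic target whose widths sit below the finite-sample peak width,
makes the optimizer destroy order indiscriminately — the quasi-greedy
default exists to prevent exactly that.

In the FDTD disorder sweep the two disorder families degrade the ≈473 nm
peak monotonically but show their broadening in different channels:
positional disorder shortens the positional coherence and broadens the
*specular* (coherent) Bragg line, while orientational disorder redirects
grain reflections to off-specular angles at slightly shifted wavelengths,
broadening the *angle-integrated* response while the surviving specular
line simply weakens. The test suite asserts each trend in its resolving
channel. At full angular disorder no visible-range peak retains more than
20% of the ordered peak's prominence.

Sweep levels: at the desk-scale ~2 µm box the finite-size peak width is
~20% of `|q1|`, so radial targets of 1–2% and azimuthal spreads inside the
Bragg angular acceptance (~2°) are not resolvable; the sweeps use
`sigma_k` ∈ {0, 4, 10}% and `sigma_phi` ∈ {0, 6, 15}° plus the isotropic
limit, chosen from the generator's S(q) response.

## Structure-factor and image analysis

`sq_points()` evaluates `S(q) = |Σ exp(i q·r)|²/N` directly;
`sq_image()` takes the normalized power spectrum of a binarized image
(Otsu threshold when needed). Both attach radial and first-shell azimuthal
profiles, skipping the forward-scattering lobe before locating the shell;
the two estimators agree on the first-shell radius within one grid step.
`autocorr_lattice()` estimates the lattice constant from the nearest
off-centre autocorrelation peak set (sub-pixel parabolic refinement,
standard error from the spread over the six peaks, anisotropy flag at 6%
radius spread — the discrete-grid spread of an isotropic image stays below
~4%). `lineprofile_spacing()` measures peak-to-peak distances along a
segment, treating each contiguous above-threshold run as one disk crossing
and discarding crossings truncated by the segment ends; in a hexagonal
lattice the answer is direction-dependent (`d` along rows, `sqrt(3) d / 2`
along the row normal), so the direction used is always reported — the two
values bracket what top-view and cross-section micrograph measurements of
the same colony produce.

## Synthetic data: what it does and does not emulate

The goniometer generator reproduces the geometric content of the
measurement — grating-equation spot positions, the tilt-streak family, the
specular dispersion, the blind region, plus Gaussian instrument kernels
(1.5°, 5 nm), per-order pointing jitter and additive intensity noise. It
does not attempt quantitative intensities (the measurement's specular lines
are stronger relative to diffraction than any of the forward models
predict, and intensity depends on domain thickness and the absorbing
substrate, which are all out of scope), speckle, or conical
(out-of-plane) diffraction. The image generator produces bright disks on
dark background with site jitter, blur and pixel noise — not the charging,
shrinkage and sectioning artefacts of real electron micrographs. Passing
recovery tests therefore demonstrate the *estimators* are unbiased at
known truth, not that real micrographs are artefact-free; the analysis of
real recordings is exactly where the published estimates from different
imaging modalities disagree with each other while goniometry remains
consistent.

## Problem sizes

Deterministic solves use: plane-wave cutoff 9, 96 k-points per leg, 24
bands; FDTD at 10 nm grid with 16384 steps on the 5 × 5 µm sample for the
perfect-lattice experiments and on ~2 µm samples for the disorder sweeps
(7 realizations per level). Stochastic recoveries use 10 seeds. These are
the sizes at which every reported quantity is converged (gap positions to
<0.1 nm against cutoff 13; FDTD peak positions to <3 nm against a 5 nm
grid; halving the box moves the perfect-lattice peaks by ~2 nm).

## Known limitations

* The FDTD is 2D TM: cells are infinite rods in cross-section; TE is
  available in the band solver where the gap structure is similar, but the
  full 3D response (and conical diffraction) is out of scope.
* Absolute reflectance intensities are not quantitative for comparison
  with experiment (no air interface, no absorbing substrate, no domain
  thickness model).
* The inverse-design optimizer matches the first reciprocal shell only;
  higher-shell correlations follow from the hard-disk constraint rather
  than from the target.
* Oblique-incidence FDTD (Bloch-periodic phase-shifted boundaries) is not
  implemented; angle-resolved forward modelling is covered by the
  transfer-matrix and band-structure routes.
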