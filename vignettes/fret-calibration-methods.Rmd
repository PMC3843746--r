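---
title: "Methods: sensitized-emission FRET calibration, ring simulations, and lifetime fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitized-emission FRET calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretcal)
```

# The measurement problem

Macromolecular machines such as the budding-yeast kinetochore or the
γ-tubulin ring complex pack tens of protein molecules into structures a few
tens of nanometers across — below the resolution of live-cell microscopy.
FRET between genetically encoded fluorophores (GFP donors, mCherry
acceptors) reports on pairwise proximities below ~10 nm, but turning raw
fluorescence into *absolute* FRET efficiency, and efficiency into distance,
requires a chain of corrections:

1. **Photometry.** Each labeled structure appears as a diffraction-limited
   cluster in a three-channel z-stack (donor, acceptor, FRET). Its
   background-corrected integrated intensity must be measured identically
   in all three channels.
2. **Spectral unmixing.** The FRET channel contains, besides true
   sensitized emission, donor bleed-through (a fraction α of the
   donor-channel signal) and directly excited acceptor fluorescence
   (a fraction β of the acceptor-channel signal). Both fractions are
   measured on single-label control cells.
3. **Normalization.** The *proximity ratio*
   `PR = (I_fret − αI_D − βI_A) / (αI_D + βI_A)` scales out integration
   time and excitation intensity (both numerator and denominator are
   linear in them), and equals the classical FRET_R metric minus one.
4. **Calibration.** A linear map from PR to absolute efficiency is
   estimated from strains with known donor–acceptor separations, whose
   efficiencies are measured independently by donor quenching: the ratio
   of mean donor intensity with acceptors present vs. absent gives
   `1 − E`, cell counts making the two means comparable because each
   cluster carries a stereotyped number of molecules.
5. **Distance.** `E = 1 / (1 + (R/R0)^6)` converts efficiency to
   separation, with `R0 = 5` nm for GFP–mCherry under the isotropic
   rotation assumption (κ² = 2/3, recorded but never computed —
   anisotropy measurement is out of scope).
6. **Maturation.** Only a fraction *m* of acceptors form a chromophore
   (~0.30 for mCherry here, estimated by lifetime analysis); donors facing
   dark acceptors are not quenched, so the apparent population efficiency
   is *m·E* and the correction is a division.

The package implements this chain (`quantify_cells()` →
`add_fret_quantification()` → `efficiency_from_donor_quenching()` →
`fit_calibration()` → `efficiency_from_proximity_ratio()` →
`correct_for_maturation()` → `forster_distance()`), plus two companion
analyses: a Monte Carlo model of donor/acceptor labeling on an oligomeric
ring (`simulate_ring()`, `scan_donor_abundance()`), and TCSPC decay
fitting (`fit_decay()`), with a synthetic-data generator
(`generate_calibration_dataset()`, `generate_decay()`) that makes every
step testable without microscope data.

# Photometry

## Conventions

Coordinates are 1-based `(x, y, z)` with pixel centers at integer
positions, matching how R indexes the matrices returned by
`tiff::readTIFF()`; a voxel array is stored `[y, x, z]`. Pixel size
defaults to 160 nm and the z-step to 200 nm.

## Focus and ROI

`find_focus_plane()` searches all z-planes for the brightest voxel within
a configurable lateral radius of a user click (the click file stands in
for the interactive GUI this procedure descends from). Ties break to the
lowest plane, then lowest row, then lowest column, so results are
deterministic.

Two ROI methods cover the two cluster geometries:

* **Metaphase (close pairs):** a 6×6 pixel box is placed within ±2 px of
  the peak to maximize its central 4×4 sum; background is
  36 × median of the 28-pixel rim of the concentric 8×8 box. The median
  (not the mean) keeps the ~5-px-distant sister cluster from biasing the
  background; the per-pixel median scaled by the 36 signal pixels is the
  only scaling that cancels a flat field exactly.
* **Anaphase (isolated spots):** a 2-D Gaussian plus constant offset is
  fitted in a window around the peak; the corrected intensity is the
  offset-subtracted sum over the elliptical contour at 2.5σ (a contour
  the source procedure leaves unstated; 2.5σ captures ≈95.6% of the spot
  mass and is configurable).

`quantify_cell()` determines focus and ROI **once**, on a reference
channel (donor by default — the brightest and most uniform channel), and
applies them unchanged to all three channels, so every channel integrates
the identical pixel set. For the Gaussian method only a per-channel
amplitude and constant background are refitted linearly with the
reference shape held fixed: the mask is byte-identical across channels
while the background level remains channel-appropriate. Quantification
uses the single in-focus plane, not a z-sum; because the PSF is common to
the channels, the plane's truncation factor cancels in every ratio the
pipeline consumes (PR, donor quenching). Negative corrected intensities
are preserved so that population averages stay unbiased.

## Measured behavior of the box method

On noiseless Gaussian spots the 6×6 box keeps ≥ 99.9% of the spot mass at
the realistic PSF width of 0.69 px (110 nm on 160 nm pixels) and ≥ 90%
through σ ≈ 1.3 px. Beyond that the box truncation and the spot tail
reaching the background rim together cost ~15% at σ = 1.5 px — a property
of the 6×6/8×8 geometry itself, which the tests characterize rather than
hide. The placement/focus search also has a selection bias on pure-noise
inputs (it picks upward noise fluctuations), bounded in tests by ~2
standard deviations of the background box sum; at realistic cluster
intensities it is below 1%.

# Spectral correction and calibration

Contamination coefficients are the means of per-cluster ratios
(`I_fret/I_donor` over donor-only cells, `I_fret/I_acceptor` over
acceptor-only cells) with standard errors of the mean; a
regression-through-origin variant was considered and rejected as the
default because the reported uncertainties of the source coefficients are
sem-style ratio statistics. GFP excited at the acceptor wavelength is
taken as zero (no third coefficient).

The calibration line is unweighted OLS of efficiency on proximity ratio
across strain/phase group means, with 95% confidence intervals from the
t-distribution on n − 2 degrees of freedom (reported unbounded for
two-point fits); an inverse-variance weighted option exists. Efficiency
uncertainty uses first-order propagation for a ratio of two sample means.
The shipped profile `gfp_mcherry_defaults()` carries α = 0.058,
β = 0.061, slope = 0.1355, intercept = 0.002, R0 = 5 nm, maturation 0.30;
note that slope·0.43 + 0.002 = 0.060265, which prints as 6.0% — reported
at full precision here, the historical 5.9% apparently coming from an
unrounded proximity ratio.

# Ring labeling Monte Carlo

The γ-TuRC-style model places 13 molecules on a 25-nm-diameter circle;
pairwise separations are exact chords `D·sin(πk/13)` (adjacent 5.98 nm,
second neighbors 11.62 nm — outside the 10-nm FRET radius, so the
within-radius graph is the ring cycle). A spacing mode
(`adjacent_spacing_nm = 6.15`, the microtubule-lattice approximation)
reproduces the 6.15-nm adjacent spacing exactly; both spacings lie within
the FRET radius, so default results are identical.

Labeling is i.i.d. Bernoulli(0.5) for the "random designation"
experiment and fixed-count (uniformly random arrangements of exactly *g*
donors) for abundance scans. Maturation thins each class independently.
Three counting rules are implemented because published descriptions of
"FRET pairs" are not mutually consistent:

* `pair_count` — every fluorescent donor–acceptor pair within the radius
  (multiple acceptors per donor all count). Unbiased labeling at full
  maturation gives 13 edges × P(mixed) = 6.5 expected pairs, and
  fixed-count labeling gives `g(13−g)/6` — maximized at the tied pair
  {6, 7}, midpoint 6.5.
* `donor_count` — donors with at least one fluorescent acceptor within
  the radius.
* `matching` — the size of a maximum bipartite matching between
  fluorescent donors and acceptors on the within-radius graph (each
  acceptor serves at most one donor). Implemented with augmenting paths;
  graphs have ≤ 13 vertices, so complexity is irrelevant, and the
  implementation is cross-checked in the tests against an independent
  igraph oracle.

**Reconciling the two published optima.** The same pair definition cannot
produce both an average of 6–7 pairs at unbiased labeling and a 3–4-donor
optimum under 25% acceptor maturation: with pairing restricted to the
10-nm (adjacent-neighbor) graph, *every* rule above peaks near balanced
abundance (the matching rule at ~5–6). The 3–4 optimum emerges from the
saturating rule when the pairing graph spans the ring
(`fret_radius_nm = 25`): expected pairs are then
`E[min(g, Binomial(13−g, 0.25))]`, which peaks at g = 3–4 — the
"equal numbers of fluorescent donors and acceptors" intuition. The
package therefore reproduces the 6.5-donor optimum with `pair_count` on
the 10-nm graph and the 3–4 optimum with `matching` spanning the ring,
and leaves the choice explicit in the configuration.

Abundance scans report all donor counts whose mean lies within one
standard error (of the difference) of the best mean, with the midpoint as
the headline optimum — this makes genuinely tied optima such as {6, 7}
representable. When the two maturation probabilities are equal and the
counting rule is symmetric under a donor/acceptor swap, the scan couples
*g* and *13 − g* antithetically (complementing the same label draws), a
common-random-numbers device that makes the exact exchange symmetry hold
exactly in the simulated means instead of only within Monte Carlo noise.
`bias_correction_factor()` is the balanced-to-biased ratio of mean pair
counts (analytically `7/(g(13−g)/6)` for the default geometry), the
multiplicative correction for proximity ratios measured under biased
incorporation.

# Lifetime (TCSPC) analysis

`decay_model()` convolves a mono- or biexponential decay with the
measured instrument response on the histogram binning. The exponential is
integrated *exactly over each time bin* rather than point-evaluated at
bin centers: point evaluation misfits the rising edge badly enough to
inflate reduced χ² to ~1.9 and bias the short lifetime, while bin
integration is the correct discrete expectation under the
piecewise-constant-IRF assumption.

`fit_decay()` maximizes the Poisson likelihood by default, initialized
from a tail log-slope (τ₂ seeded at τ₁/3, amplitudes by linear least
squares) refined through a Levenberg–Marquardt Neyman-weighted least
squares stage. Pure Neyman least squares (`method = "neyman"`) is kept as
an option, but at 10⁵ photons over 256 bins it underestimates the short
lifetime by 4–7% — a known small-count artifact of weighting by observed
counts — so the likelihood fit is the default. The reported reduced χ² is
the conventional Neyman-weighted statistic in either case; components are
ordered τ₁ ≥ τ₂. `fraction_with_acceptor()` returns A₂/(A₁+A₂), the
FRET-quenched donor fraction, and `efficiency_from_lifetimes()` returns
1 − τ₂/τ₁. Model order (1 vs 2 components) is deliberately the caller's
choice; `compare_decay_fits()` provides an F-test but never auto-applies
it. The IRF is treated as a fixed measured curve — no shift, jitter, or
color-shift parameters.

# The synthetic-data generator

`cell_truth()` describes a dividing cell with two clusters of
`n_pairs = 128` labeled molecules (16 kinetochores × 8), separated by
800 nm in metaphase or 4.5 µm in anaphase. Per-cluster brightness
multipliers are truncated normals with sd 0.114 (donor) and 0.166
(acceptor) — the measured cluster-to-cluster variabilities, applied per
cluster because the source scatter is per-cluster. Acceptor maturation is
Binomial per cluster; donor maturation is fixed at 1 (donor variability
shows no maturation signature). The intensity model is the algebraic
closure of the correction chain, so noiseless datasets recover their
parameters *exactly*, and incomplete maturation produces precisely the
apparent-efficiency dilution that `correct_for_maturation()` undoes. The
sensitized-detection factor γ defaults to 1 (the proximity-ratio
normalization absorbs detection-efficiency asymmetries) and is exposed
for sensitivity tests.

Rendering places 3-D Gaussian spots (σ_xy 110 nm, σ_z 300 nm — realistic
for a 1.4-NA objective and GFP emission, chosen as fixtures rather than
claims about any particular instrument) on the 160/200-nm grid with
sub-pixel jitter, Poisson shot noise, a 100-count camera offset and
2-count Gaussian read noise. Brightness defaults to 2000 counts per
fluorophore: bright, low-shot-noise clusters are the regime in which
per-mille-level contamination coefficients are measurable at all, and at
this level the ROI search's noise-selection bias stays below 1%.

What the generator does **not** emulate: non-Gaussian PSF structure,
flat-field and chromatic inhomogeneity, focal drift, photobleaching,
cytoplasmic autofluorescence gradients, and cluster shape irregularity.
Passing closure tests therefore demonstrate the correctness of the
estimators under the stated noise model, not robustness to every
real-microscope artifact.

The generator-implied calibration (`implied_calibration()`) applies the
correction arithmetic to the *noiseless truth intensities* of a rendered
dataset. Pipeline-recovery tests compare against this conditional truth
because it isolates what the measurement chain should recover from the
finite-sample variability of the brightness draws themselves: under the
study's variability (σ 0.114/0.166) the *population* slope of a
3-strain × 170-cell experiment fluctuates by ~5% between replicate
experiments, so an unconditional comparison at that tolerance would test
luck, not code.

# Problem sizes and numerical choices

The test suite runs ring simulations at 4,000–10,000 replicates
(exhaustive enumeration over all C(13, g) arrangements as the oracle),
calibration closures at 3 × 100 FRET cells plus 2 × 100 control cells,
and lifetime recovery over 100 decays of 10⁵ photons on 256 bins over a
12.5-ns window — sizes chosen to keep Monte Carlo standard errors well
below the tolerances being asserted. Gaussian photometry fits use
Levenberg–Marquardt with amplitude bounded below by zero and σ bounded
away from zero; degenerate (flat) inputs raise a classed `fit failed`
condition, which `quantify_cell()` converts to a flagged zero-signal row
so that batch quantification never aborts mid-dataset. Proximity ratios
with a non-positive contamination denominator raise a classed error
naming the cluster. Seeded entry points (`simulate_ring()`,
`scan_donor_abundance()`, `generate_calibration_dataset()`,
`generate_decay()`) save and restore the caller's RNG state.

# Known limitations

* Distances assume isotropic fluorophore rotation; κ² is a recorded
  assumption and anisotropy is out of scope.
* The proximity ratio depends on the labeling stoichiometry; the
  calibration transfers only to structures whose FRET-pair count is
  proportional to total donor+acceptor numbers, and
  `bias_correction_factor()` addresses only the ring-geometry case.
* Single-plane photometry underestimates absolute integrated intensity
  by the plane fraction; all pipeline quantities are ratios in which the
  factor cancels, so absolute molecule counting is not supported.
* The FLIM module fits decays pooled per strain, not per-pixel lifetime
  images.
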