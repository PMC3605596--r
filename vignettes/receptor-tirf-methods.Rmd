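---
title: "Simulating and analyzing single-molecule TIRF recordings of membrane receptors"
author: "tirftrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing single-molecule TIRF recordings of membrane receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirftrack)
```

## The scientific problem

G-protein-coupled receptors such as the M2 muscarinic acetylcholine
receptor signal through encounters with other membrane proteins — for the
M2 receptor, with GIRK potassium channels whose opening slows the
heartbeat. How fast that signal can possibly propagate is set by how many
receptors sit in the membrane (surface density, &rho;, in um^-2^), how fast
they move (the lateral diffusion coefficient D~lat~, um^2^ s^-1^), and
whether they act as monomers or oligomers. All three quantities can be read
out of single-molecule total internal reflection fluorescence (TIRF)
movies, in which each labeled receptor appears as a diffraction-limited
spot (~300 nm FWHM) that can be localized to ~25 nm, tracked while it
diffuses, and watched until it photobleaches in a single step.

`tirftrack` implements that entire measurement chain twice over: once as a
*generator* that simulates TIRF movies with known ground truth, and once as
an *analysis pipeline* (spot detection, tracking, mean-squared-displacement
analysis, photobleaching-step counting, density estimation) whose accuracy
can therefore be demonstrated by parameter recovery rather than asserted.
A separate Monte Carlo module turns the measured densities and mobilities
into a predicted receptor–channel collision rate and signaling latency.

## The synthetic-movie generator

`simulate_movie()` renders what the analysis modules assume about real
data:

* **Placement and motion.** Particles are placed uniformly at density
  &rho; (Poisson-distributed count) and mobile particles take Gaussian
  steps with per-axis variance 2 D~lat~ &Delta;t per frame. Boundaries are
  periodic; the wrap count is recorded in the ground truth so trajectories
  can be unwrapped exactly.
* **Optics.** Each unbleached fluorophore contributes an integrated 2-d
  Gaussian PSF with &sigma; = FWHM / 2.3548 (default FWHM 0.3 um) at its
  continuous position; pixels are 0.1 um by default, matching a 5 x 5
  pixel = 500 x 500 nm^2^ intensity-measurement window.
* **Noise.** Signal photons are Poisson; the camera background has a mean
  offset plus Gaussian read noise. The defaults (600 photons per spot per
  frame, background 100 +/- 6 counts/pixel) give ~20 nm centroid precision
  and make single bleaching steps visually obvious; no published noise
  model exists for the original recordings, so this SNR is the package's
  own choice and all quantitative tests state it explicitly.
* **Photophysics.** Each fluorophore bleaches after an exponential waiting
  time (rate `bleach_rate`) and never re-emits; blinking is deliberately
  not modeled.
* **Dimerization.** Monomer pairs within a capture distance (50 nm)
  associate with the discrete-time probability implied by a 2-d
  mass-action rate constant k~on~ (um^2^ s^-1^) and dissociate at k~off~
  (s^-1^, default 1 s^-1^, the observed ~1 s dwell of doubled-intensity
  episodes). Dimers are rendered as two coincident point sources — one
  spot of double intensity — and move as one random walker. The
  equilibrium is pre-run before frame 0 so illumination starts from the
  stationary monomer/dimer mixture. Immobile nonspecific spots share the
  same bleaching kinetics but neither move nor dimerize.

What the generator does **not** emulate: EMCCD gain statistics, the
evanescent-field axial intensity profile, motion blur within a frame,
blinking, and cell-shaped footprints (the field is uniformly labeled).
Parameter recovery on these movies therefore demonstrates the correctness
of the analysis arithmetic and its robustness at realistic SNR, not
robustness to every artifact of real hardware.

## Spot detection and tracking

Detection finds local maxima of a 3 x 3 box-smoothed frame above a
threshold of 5 robust noise SDs; background and noise are estimated by
sigma clipping so that crowded frames do not inflate the threshold. Each
candidate is refined by intensity centroiding over the 5 x 5 window after
local background subtraction (median of the surrounding ring), which
reaches ~20 nm RMS at the default SNR — inside the 25 nm the measurement
model assumes. The frame is extended periodically before processing so
edge spots are counted; two detections closer than the PSF FWHM (0.3 um)
cannot be resolved and are merged by construction.

Linking is greedy nearest-neighbor, resolved globally per frame pair by
ascending distance; at the densities where tracking is meaningful
(&le; ~1 um^-2^) this matches ground-truth identities in &ge;90% of links,
and full bipartite optimization was deliberately left out. The default
linking radius is 3 sqrt(4 D~max~ &Delta;t) with D~max~ = 1 um^2^ s^-1^ —
generous enough for the fastest receptors reported in tissue; when the
expected mobility is known, passing it as `d_max` tightens the radius and
reduces wrong links. No gap closing is done by default (blinking is not
modeled). Tracks shorter than 5 frames are dropped as too short for an
MSD fit.

A practical caveat discovered by simulation and worth stating: when two
spots approach within the PSF width their images coalesce and the merged
centroid jumps. At &rho; = 0.5 um^-2^ these events inflate a D~lat~ of
0.1 um^2^ s^-1^ by ~7–9%; at &rho; = 0.2 um^-2^ the bias is below 3%.
Mobility measurements (and their tests) are therefore run on sparse
fields, which is also how such experiments are designed; density above the
countable limit is instead measured by bleach extrapolation (below).

## Mobility analysis

`msd_curve()` pools time- and ensemble-averaged squared displacements over
all overlapping frame pairs at each lag; `fit_dlat()` fits a weighted line
through the first 4 lags (a common single-particle-tracking default) and
reports D~lat~ = slope / 4. The intercept is left free: independent
localization errors add a constant 4 &sigma;~loc~^2^ &asymp; 0.0025 um^2^
to every lag, which a free intercept absorbs without biasing the slope.
`classify_motion()` fits the log–log slope &alpha; of the MSD curve and
calls motion free for &alpha; in 1 +/- 0.15, directed ("flow") above,
confined ("caged") below; the 0.15 band keeps misclassification of pure
Brownian input below 5% at paper-scale track counts. Temperature series
are fitted by `fit_temperature()` to D(T) = D~ref~ exp(k (T - T~ref~)),
reporting Q10 = exp(10 k); membrane-protein mobility typically has Q10
&asymp; 2, and the fit recovers an exact doubling rule to machine
precision.

## Photobleaching-step stoichiometry

Intensity traces are 5 x 5-window means (counts/pixel) at the tracked
position, background-subtracted, and extended a few frames past the track
end so the terminal drop to background is part of the trace. The chain is:
3-point running median (`median_smooth()`, endpoints passed through), a
5-point central first derivative, candidate transitions at derivative
extrema, and piecewise-constant level fitting between transitions
(`detect_steps()`). Because one derivative sample has limited SNR,
candidates are collected at half the nominal threshold and validated by a
z-test on the separation of the fitted levels on either side (up to 10
frames per side) at the full threshold (default 4 robust SDs); the level
test pools many frames, so at 20% noise a two-step staircase is recovered
with both transitions within +/-2 frames in &ge;95% of traces while a
constant noisy trace stays transition-free in &ge;99%. Derivative noise is
estimated from lag-3 trace differences (MAD-based), which clears the
median filter's correlation length and is insensitive to the steps
themselves; the calibration constants (1.2 between the lag-3 scale and the
derivative SD, 1.5 inflation of the level-mean SE for filter-induced
correlation) were fixed once against median-filtered Gaussian noise.

`classify_trajectory()` maps fitted levels onto integer multiples of a
single-fluorophore unit intensity (calibrated as the mode of the
spot-intensity histogram) with a +/-35% tolerance — wide enough to absorb
shot noise at the default photon budget, narrow enough to separate one
fluorophore from two. The taxonomy: one unit ending in a single drop to
background is a monomer (`type1`); two sequential unit drops, a bleaching
dimer (`type2`); a rise from one to two units before the fall, a dimer
forming mid-track (`type3`); other one/two-unit alternation patterns are
binned together as `dimer_other` rather than guessed at; three or more
units raises the `higher_oligomer` flag. On simulated movies with
monomer–dimer kinetics the type-1 fraction falls from ~79% at
1.5 um^-2^ to ~59% at 3 um^-2^ with identical kinetics — expression level
alone shifts the apparent stoichiometry, the signature of a reversible
first-order equilibrium.

`coincidence_null()` is the Monte Carlo null for apparent dimers: how many
tracks of *independently* diffusing particles would show a doubled-spot
episode by chance overlap of their PSFs? A minimum sustained-overlap
duration (`min_overlap_s`, default 1 s, matching the dwell of genuine
doubled-intensity episodes) defines an "episode": at 0.15 um^2^ s^-1^ two
independent walkers separate from a 0.3 um coincidence in tens of
milliseconds, so sustained chance coincidences are essentially absent
(fraction &lt; 0.10 at 1.5 um^-2^) and observed ~1 s episodes cannot be
chance overlap. With `min_overlap_s` of one frame the function instead
reports the (much larger, density-increasing) instantaneous coincidence
fraction.

## Density estimation

Direct spot counting (`count_density()`) is reliable below 0.8 um^-2^;
above that, PSF overlap merges spots and the estimate is flagged rather
than trusted. Higher densities are recovered by photobleaching
extrapolation: the bulk bleaching rate k is fitted to the summed field
intensity (`fit_bleach_rate()`), and once bleaching has thinned the
observable density below 0.5 um^-2^ the late-frame counts are pooled with
the Poisson maximum-likelihood back-extrapolation
&rho;~0~ = &Sigma; N~i~ / (A &Sigma; e^(-k t~i~)) (`bleach_extrapolate()`).
The usable window starts after the *last* crossing of the count limit,
because early crowded frames can undercount so badly that they dip below
the limit spuriously. Two honest limitations, quantified by simulation:
the surviving-particle bottleneck makes a single-movie estimate ~12–15%
noisy regardless of estimator (the information is carried by the ~50–100
particles alive when the window opens), and residual PSF merging costs a
few percent downward bias; recovery demonstrations therefore average a
small number of replicate movies and use a 14 x 14 um field.

For tissue with heterogeneous expression, `tissue_average_density()` is
the trivial but easily-misread product: 10% of cells expressing at
2 um^-2^ is a tissue average of 0.2 um^-2^, which is what bulk
radioligand assays measure.

## The collision simulation

`simulate_collisions()` random-walks receptors and channels in a periodic
box and scores an encounter when a pair's separation first falls below the
collision radius b = 6 nm from outside. Two numerical rules matter:

* **No tunneling.** The per-step relative displacement must satisfy
  sqrt(2 (D~R~ + D~G~) dt) &le; b/2, or pairs step across the capture disc
  unseen; the configuration refuses to run otherwise. At the default
  parameters this forces dt &asymp; 2.25 us, i.e. ~0.9 million steps per
  simulated second, so the inner loop is compiled (Rcpp) and uses a Verlet
  pair list with a skin wide enough that an unlisted pair cannot reach the
  capture disc between rebuilds.
* **Encounter definition.** A 2-d random walk is recurrent: a pair parked
  just outside 6 nm re-crosses it many times before truly separating, so
  re-arming at a distance of order b counts one diffusive encounter
  several times over (measured: ~5x at 2 b). A pair is therefore re-armed
  only after separating beyond 0.3 um — the scale at which the two
  molecules become optically distinguishable again and comparable to the
  spacing to the *next* nearest partner, i.e. the point where "the same
  encounter" has genuinely ended. The escape radius remains a parameter.

At the tissue parameters (both species at 3 um^-2^, each at 1 um^2^ s^-1^
— the 37 °C extrapolation of the measured mobilities — b = 6 nm), the
simulation gives ~8.5 encounters per receptor per second and a mean first-
encounter latency of ~0.14 s, consistent with the time-dependent 2-d
Smoluchowski comparator k(t) &rho; = 4&pi; D~rel~ &rho; / ln(4 D~rel~ t / b^2^)
&asymp; 6 s^-1^ (2-d rates are only logarithmically defined, so agreement
within ~1.5x is the meaningful check). The first-encounter latency is the
quantity that bounds signaling speed: it is insensitive to the re-arming
choice and sits near 1/rate, ~150 ms — the same order as the measured
latency between acetylcholine application and GIRK current onset.

## Ligand occupancy

`fractional_occupancy()` and `competition_curve()` are the standard 1:1
equilibrium expressions (occupancy L/(L + K~d~); single-site competition
with Hill slope 1 and Cheng–Prusoff IC50). Ligand depletion is ignored
(free &asymp; total), appropriate for nanomolar ligand on the few thousand
sites of a cell footprint. Affinities are stored as log10 values and K~d~
derived, matching how such affinities are reported. At 10 nM a ligand
with log affinity 10.35 (K~d~ &asymp; 45 pM) occupies 99.56% of sites —
the arithmetic behind labeling ">99.5%" of receptors — and one with log
affinity 8.83 occupies 87.1%.

## Problem sizes and determinism

All stochastic functions take an explicit seed and every simulation
records it, so reports are byte-for-byte reproducible. The demonstration
sizes used in the test suite — 40 x 40 um sparse fields (&ge;300 tracks)
for mobility recovery, four replicate 14 x 14 um movies per density for
bleach extrapolation, 400-trace sweeps for the step detector, five 2-s
replicates of a ~100-receptor box for the collision bracket — were chosen
as the smallest sets at which the quoted tolerances are comfortably
resolved by the statistics above.

## Known limitations

* The tracker is single-hypothesis; at densities well above 1 um^-2^
  identity errors grow and mobility estimates inflate (quantified above).
* Step counting assumes a stable unit intensity; strong focal drift or
  axial motion (not modeled by the generator) would smear the unit grid.
* The collision rate, unlike the latency, depends on what one calls "one
  collision"; both the re-arming distance and the analytic comparator are
  exposed so that sensitivity can be checked rather than trusted.
* Bleach extrapolation inherits the realized randomness of a single
  photobleaching history; replicate movies, not longer ones, are the
  effective remedy.
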