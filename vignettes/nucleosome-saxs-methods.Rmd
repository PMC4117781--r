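---
title: "Models and methods behind nucsaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucsaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nucsaxs analyses salt-induced disassembly of nucleosome core particles
(NCPs) with small-angle X-ray scattering (SAXS) under sucrose contrast
variation, at equilibrium and in stopped-flow time series. This vignette
documents the models, the numerical choices, and the boundaries of what the
synthetic-data generator can and cannot establish. Everything quantitative
stated here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is asserted beyond what those runs show.

## The coarse-grained DNA model

Nucleosomal DNA is represented by two backbone beads per base pair, placed
diametrically at `duplex_radius` (10 Å) about the local duplex axis and
rotated by `twist_per_bp` (34.3°) per step. The fully wrapped state winds
this duplex along a left-handed superhelix with the canonical nucleosome
geometry: radius 41.9 Å, pitch 25.9 Å per turn, 1.65 turns for 147 bp.
Partially released states keep a central superhelical arc and append rigid
straight arms leaving tangentially at the release points; the fully
released state is a straight 3.4 Å/bp B-form duplex.

Two geometric subtleties are deliberate:

* **Arc spacing.** DNA bent onto the nucleosomal superhelix advances about
  3.0 Å per bp along the path — the 437 Å arc of the canonical superhelix
  carries 147 bp — so wrapped base pairs are spaced by arc length, while
  `rise_per_bp` (3.4 Å) governs straight segments. Forcing 3.4 Å/bp along
  the arc would distort the superhelix radius by over 10%.
* **Pair smearing.** Discrete beads imprint the helical repeat on the
  pair-distance histogram as a comb of spikes. `pofr_from_model()` therefore
  smears each pair distance by the Gaussian bead width (3 Å by default,
  matching the optional smearing in `debye_profile()`), restoring the smooth
  distribution of the underlying continuous duplex. With smearing, the free
  duplex shows its short-range peak at 20 Å (the duplex diameter, d1) and
  the J-shaped intermediate its wrapped-diameter peak at 80 Å (d3).

A known limitation follows from the two-bead representation: all DNA mass
sits on the backbone shell, so bead distances from the superhelix axis
spread between 32 and 52 Å. This splits the wrapped-structure chord feature
into an inner (~69 Å) and a cross (~83 Å) hump whose smoothed maximum lies
near 75 Å, where an all-atom model — with duplex mass extending inward —
shows the d3 feature at ~80 Å. No two-bead radial placement can satisfy
both d1 = 20 Å (which pins the backbone radius at ~10 Å) and d3 = 80 Å; we
keep the physical geometry and accept the 6% shift, which the acceptance
run reports honestly.

The default candidate pool holds 32 members: all unordered release pairs
over the levels {0, 12, 24, 37, 49, 61, 73} bp that keep at least a 2 bp
arc (27 members; mirror images are removed because P(r) cannot distinguish
left- from right-end release), plus single-ended deep releases of 85, 92,
110, 128 and 147 bp. Symmetry classification uses a 10 bp tolerance:
`wrapped` below 10 bp release on both ends, `free` within 10 bp of complete
release, otherwise `symmetric`/`asymmetric` by whether the two ends differ
by more than 10 bp.

The optional protein core is 8 pseudo-histone beads (16000 Å³ each,
octamer-scale total volume) on a ring about the superhelix axis. It exists
for contrast and I(0) bookkeeping — forward intensities add as squared
weight sums — not as a structural octamer model.

## Contrast

Solvent, protein and DNA phases carry electron densities 0.334, 0.42 and
0.55 e/Å³. A bead's scattering weight is (ρ_phase − ρ_solv) × volume.
Sucrose raises ρ_solv linearly; the slope is calibrated so 50% sucrose
(weight fraction 0.5) matches the protein exactly, blanking it from the
scattering. NaCl also raises ρ_solv (+0.009 e/Å³ per mol/L). Because
matching buffers are prepared per condition at a beamline, the simulators
default to `contrast_model(match_salt = salt)` — the 50% sucrose match
holds at the working salt, as the experiments that motivated this package
demonstrated at 2 M NaCl. With a fixed 0 M calibration instead, the 16000 Å³
protein beads would carry a spurious −0.017 e/Å³ residual at 1.88 M that
changes the contrast-matched I(0) by tens of percent.

## Scattering and the two P(r) routes

Theoretical profiles use the Debye sum over bead pairs,
I(q) = Σᵢⱼ wᵢwⱼ sin(q rᵢⱼ)/(q rᵢⱼ), on a 200-point log-spaced grid over
0.007–0.25 Å⁻¹ (the experimentally usable range). Point beads are valid in
this q range; Gaussian smearing multiplies I(q) by exp(−(qσ)²) and leaves
I(0) unchanged. The same pair set, histogrammed, gives the real-space
reference P(r); the tests require the two routes to agree to numerical
precision, and the regularized inversion of the Debye profile to agree with
the histogram to 5% L2 at the band-limited resolution (~π/q_max ≈ 13 Å).

P(r) follows the forward-scattering convention 4π∫P dr = I(0), with
rg² = ∫r²P dr / (2∫P dr). For histograms from bead models the recorded Rg
and I(0) attributes are the exact bead-model moments (including the
self-correlation mass that the pair-only curve omits); the distinction
matters only below a few dozen beads.

## Regularized inversion and Dmax selection

`ift_regularized()` minimizes the σ-weighted residual plus
α‖second difference of P‖², subject to P ≥ 0 and P(0) = P(Dmax) = 0, on a
201-point r-grid. The non-negative solve uses Lawson–Hanson NNLS on the
stacked system. α defaults to a discrepancy-principle rule: the largest
value on a log grid (10⁻⁷–10³) whose unconstrained solution keeps the
reduced χ² within 10% of its minimum, and at least at 1. We found the
classical L-curve corner unreliable here — the curve is smooth for these
kernels and the corner can land orders of magnitude too high — while the
discrepancy rule behaves identically for noisy and noiseless input.

`scan_dmax()` operationalizes the usual three qualitative criteria with
explicit thresholds, all exposed as arguments: (i) reduced χ² within 1.2×
the best over the scan; (ii) P(r) shape stabilized, relative L2 change
below 5% against the adjacent candidate; (iii) a smoothly decaying tail,
non-increasing within 2% of the peak over the last 10% of [0, Dmax]. The
smallest passing candidate wins; if none passes the best-χ² result is
returned flagged `unstable`. On the wrapped model this recovers Dmax within
10%; on free DNA with 0.5% noise it reaches ~460 Å against a true 504 Å —
Dmax under low-q truncation is systematically soft, which is why the
acceptance value for the free-DNA extent is computed from the model
geometry, not the scan.

## Feature calling

`detect_peaks()` smooths P(r) (5 grid points for model histograms, 9
recommended for noisy experimental curves) and reports the most prominent
local maximum in each window: d1 10–30 Å (duplex diameter), d2 30–55 Å
(overlapping DNA ends), d3 55–100 Å (wrapped-structure diameter), with a
prominence threshold of 5% of the global maximum. `call_state()` maps
patterns to states: d2∧d3 with Dmax < 150 Å → `wrapped`; d3 without d2 and
Dmax > 250 Å → `intermediate_J`; d1 without d3 and Dmax > 400 Å →
`unwrapped`; otherwise `ambiguous`.

Two caveats are documented rather than patched. First, the coarse model's
end-overlap distances sit near one superhelical pitch (~27 Å), below the
30–55 Å d2 window, so the fully wrapped member calls `ambiguous`; the
window is kept where the experimental assignment puts it. Second, the
pipeline-consistency test scores state calls against geometric expectations
only where one exists: an intermediate call is expected when Dmax > 250 Å
*and* the retained arc is at least 45 bp (half a superhelical turn — less
than that is not a recognizable "J"), an unwrapped call when the arc is
below 20 bp and Dmax > 400 Å. Measured agreement is 12/13 members, the
wrapped member being the logged exception. P(r) mirror symmetry makes
left/right release indistinguishable, so asymmetry quantification is
delegated to the ensemble fit.

## Ensemble fitting

`select_ensemble()` fits data with non-negative weights over the 32 pool
profiles by NNLS, truncates to the largest `max_members` (default 4),
drops weights below 1% and refits. For a pool this small NNLS is exact, so
the genetic-algorithm machinery of classical EOM is unnecessary; we solve
the same optimization directly and reproducibly. Reported weights sum to
one with the intensity scale separate; χ² is per degree of freedom. Members
whose σ-weighted profiles differ by less than ~1σ per point are reported as
degenerate pairs instead of silently splitting weight. The asymmetric
fraction is the weight on members classified asymmetric; on synthetic data
built from majority-asymmetric ensembles it exceeds 0.75, a
construction-validity check rather than a reproduction of experiment.

## Kinetics

The synthetic schemes encode the two constructs' disassembly:

* **601** (strong positioning): wrapped NCP →(burst opening, 0.2 s hold)→
  J-shaped DNA with the disrupted core still bound →(0.74 s⁻¹)→ free DNA +
  dissociated protein. The hold reproduces the observed ~200 ms plateau;
  the burst step is instantaneous (complete within the mixer dead time) and
  is represented by a leading infinite rate after the lag.
* **5S** (weak positioning): wrapped NCP →(41.6 s⁻¹)→ extended DNA with a
  partially bound core (one histone dimer already released) →(1.13 s⁻¹)→
  fully dissociated. Whether the fast phase is protein release or DNA
  unwrapping is left open; the scheme encodes it as the first kinetic step
  without asserting mechanism.

Species fractions follow the sequential first-order closed form (Bateman),
and frames are fraction-weighted species profiles plus 2% relative Gaussian
noise (the default `noise_model()`; Poisson noise applies only to detector
rendering). All printed rate values are treated as rate constants in s⁻¹.

`trace_i0_rg()` extracts I(0,t) by default as the mean intensity over the
lowest 15 q points — a *linear* functional of the profile, so mixtures of
interconverting species keep exactly exponential kinetics even though the
absolute extrapolation is biased for very large particles. (A Guinier
intercept is log-nonlinear and measurably biases fast-rate estimates; the
full P(r) route is available as `method = "pofr"` and is what the
contrast-matched flat-I(0) check uses.) Exponential fits run
Levenberg–Marquardt from decade-spaced multi-starts with rates bounded
positive; double-exponential starts require a rate ratio above 2.
`model_selection()` prefers two exponentials only when the reduced χ²
improves by more than 15% and the smaller amplitude exceeds 3 standard
errors. Across 20 seeds at default noise the recovered 601 rate is unbiased
within 5% with calibrated uncertainties.

`svd_analysis()` decomposes the q×time matrix with rows weighted by their
mean σ and counts components whose singular value exceeds 3× the noise
floor (median singular value) and whose q- and time-vectors both have lag-1
autocorrelation above 0.6. The thresholds are package choices; rank equals
species count on noiseless series and the three-species schemes show at
least two significant components at 1% noise.

## Detector reduction

`azimuthal_average()` bins unmasked pixels into q annuli with
σ = sd/√N_pixels per annulus; `normalize_and_subtract()` applies monitor
normalization and buffer subtraction with quadrature errors;
`average_repeats()` pools repeats by inverse variance and warns when they
are mutually inconsistent. Polarization and solid-angle corrections are
omitted — negligible at ≤ 0.25 Å⁻¹ and ~1 m geometry. Radiation damage is
monitored as a per-frame correlation drift statistic, never auto-rejected.

## What the synthetic data do and do not establish

The generator emulates: equilibrium titrations over 0.2–2.0 M NaCl at 0%
and 50% sucrose (with per-salt matched buffers), 20 ms stopped-flow frames
over 0.02–60 s, the two kinetic schemes above, Gaussian profile noise and
Poisson detector counts, with every ground-truth quantity recorded in
manifests. It does **not** emulate: inter-particle interference at low
salt, sequence-specific DNA mechanics (601 vs 5S differ only through
kinetic and ensemble parameters), conformer flexibility beyond the rigid
pool, hydration-shell scattering, beam smearing, or radiation damage.
Passing tests therefore demonstrate that the analysis chain recovers known
inputs under realistic noise — not that it would be immune to those real-world
effects.

## Problem sizes

The shipped tests and acceptance script run at the sizes a laptop handles
comfortably: 294–600-bead models, 200-point q grids, 32-member pools,
kinetic series of 150–3000 frames binned to 8–12 time points, 6–20 seeds
per stochastic check. The full suite completes in under ten minutes on one
CPU; the acceptance script in about three.
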