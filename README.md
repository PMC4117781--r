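# nucsaxs

Analysis of salt-induced nucleosome core particle (NCP) disassembly with
contrast-variation small-angle X-ray scattering (SAXS), at equilibrium and
in stopped-flow time series.

The NCP wraps 147 bp of DNA in ~1.65 left-handed superhelical turns around
a histone octamer. Raising NaCl releases the DNA through transient,
partially unwrapped intermediates. SAXS reports on this through three
quantities: the forward intensity I(0) ∝ (Σ excess electrons)², which
tracks protein dissociation; the radius of gyration R_g; and the
pair-distance distribution P(r), obtained by regularized indirect Fourier
transform of I(q), whose diagnostic length scales identify the DNA
conformation — d1 ≈ 20 Å (duplex diameter), d2 ≈ 40 Å (overlapping DNA
ends), d3 ≈ 80 Å (wrapped-structure diameter). Adding 50% sucrose raises
the solvent electron density to match the protein, blanking it so only DNA
scatters.

The package provides, as a tidyverse-style API (tibbles in and out,
`tidy()`/`glance()`/`autoplot()` methods):

* coarse-grained bead models of nucleosomal DNA — wrapped, partially
  released (symmetric, asymmetric, "J"-shaped), and free — plus a
  32-member candidate pool (`build_wrapped()`, `build_released()`,
  `generate_pool()`);
* Debye-sum theoretical profiles under a three-phase contrast model with
  sucrose protein matching (`debye_profile()`, `contrast_of()`,
  `kratky()`);
* regularized P(r) inversion with a three-criterion Dmax scan and derived
  R_g/I(0) (`ift_regularized()`, `scan_dmax()`, `pofr_from_model()`);
* d1/d2/d3 feature detection and wrapped/intermediate/unwrapped state
  calls (`detect_peaks()`, `call_state()`);
* ensemble fitting of profiles with non-negative pool weights and the
  asymmetric fraction (`select_ensemble()`, `asymmetric_fraction()`);
* time-resolved analysis: mixing arithmetic, time binning, kinetic SVD,
  I(0,t)/R_g(t) traces, single/double exponential rate fits
  (`mixing_concentration()`, `bin_time()`, `svd_analysis()`,
  `fit_exponential()`, `model_selection()`);
* 2-D detector reduction (`azimuthal_average()`,
  `normalize_and_subtract()`) and a synthetic-data generator with recorded
  ground truth (`simulate_disassembly()`, `simulate_equilibrium_series()`,
  `fixture_bundle()`).

## Worked example

Build the wrapped NCP DNA, compute its contrast-matched profile, invert to
P(r), and read off the structural features:

```r
library(nucsaxs)

ncp <- build_wrapped(147)
ncp
#> <conformer 'wrapped_147bp'> 294 beads, 147 bp, released L=0 R=0 (wrapped)

p  <- debye_profile(ncp, sucrose = 0.5)              # DNA-only contrast
pr <- scan_dmax(saxs_profile(p$q, p$I, sigma = 0.01 * p$I),
                candidates = seq(80, 200, by = 15))
glance(pr)
#> # A tibble: 1 × 7
#>    dmax    rg         i0  chi2    alpha method n_flags
#> 1   110  44.3 131369453. 0.378 0.000316 ift          0

detect_peaks(pr)
#> # A tibble: 3 × 4
#>   feature present location prominence
#> 1 d1      FALSE       NA           NA
#> 2 d2      FALSE       NA           NA
#> 3 d3      TRUE        75.4          1
```

The scan selects Dmax = 110 Å (the model's true maximum extent is 112 Å)
and R_g = 44.3 Å, matching the compact NCP; the P(r) shows the
wrapped-structure diameter peak (d3) and, being fully wrapped, extends no
further than ~110 Å.

Simulate a stopped-flow disassembly of the strong-positioning construct
(hold ~200 ms, then first-order protein release) and refit the rate from
the I(0,t) trace:

```r
ts  <- simulate_disassembly(scheme_601(), times = seq(0.02, 20, by = 0.02),
                            seed = 1)
tr  <- trace_i0_rg(ts)
fit_exponential(tibble::tibble(time = tr$time, value = tr$i0),
                n_exp = 1, t_min = 0.2)
#> <kinetic_fit> 1-exponential, reduced chi2 2.6e+12
#>   k1 = 0.7398 +/- 0.0014 1/s (amplitude 3.7e+08)
#>   baseline 2.89e+08
```

The fitted rate, 0.740 s⁻¹, recovers the generating dissociation rate of
the scheme (0.74 s⁻¹). (The reduced χ² is large only because this quick
trace carries no per-point uncertainties; weighted fits return calibrated
values.)

`run_pipeline(seed)` chains the whole analysis — equilibrium salt series →
P(r)/features/ensemble per salt, plus both kinetic constructs → SVD,
traces and rate fits — and writes a summary JSON.

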