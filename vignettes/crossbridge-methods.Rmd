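---
title: "Methods: a metabolite-sensitive cross-bridge model and its frequency-domain fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a metabolite-sensitive cross-bridge model and its frequency-domain fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xbkinetics)
```

## The model and its assumptions

`xbkinetics` implements a three-state stiffness-distortion model of cardiac
cross-bridge cycling.  Myosin heads are detached (**A**), attached
pre-power-stroke (**B**) or attached post-power-stroke (**C**); the state
variables are the occupancies `B` and `C` and the mean elastic distortions
(strains) `xB` and `xC` of the attached populations.  Stress is the product
of a collective myosin stiffness `K` with the summed distortion
`B xB + C xC`, plus a cross-bridge-insensitive spring `Ks` engaged beyond
the 1.9 µm slack length.  The model assumes full thin-filament activation
(saturating Ca²⁺, as in a pCa 4.5 activating solution): there is no
calcium-regulation layer.  Length dependence enters only through the
availability `Z(L)`, linear below the optimum `Lmax = 2.3` µm and flat on
the 2.3–2.4 µm plateau; the descending limb is outside the model's domain
and lengths above 2.4 µm are rejected.

The mean-strain equations are first-moment reductions of a
distribution-of-strain picture: attachment and slipping pull the mean
strain of a population toward its reference value (0 for `xB`, the
power-stroke displacement `xC0 = 0.01` µm for `xC`) at a rate `ϕx` times
the per-capita entry flux, while imposed sarcomere velocity advects both
strains with gain `ϕv`.  Cross-bridges entering **B** from **C** pull the
mean strain toward zero exactly as printed in the source equations; no
carried-distortion term is included, since the fitting data (small
perturbations about a steady state) cannot distinguish the variants.

### Metabolite dependence

Two schemes make the cycle sensitive to ATP and inorganic phosphate:

* **Method 1 (direct):** the metabolite is folded into a pseudo-first-order
  rate, `k−1 = k−1′ [Pi]`, `k3 = k3′ [ATP]`.  The primed constants then
  carry units of s⁻¹·mM⁻¹, and the parameter table of every permutation
  records its units so fitted values cannot be cross-interpreted.
* **Method 2 (rapid equilibrium):** binding is a fast sub-step with
  dissociation constant `kd`, and both rates leaving the binding state are
  scaled by saturation fractions (`k−1 = k−1′ [Pi]/(kdPi+[Pi])`,
  `k2 = k2′ kdPi/(kdPi+[Pi])`, and the ATP analogues on `k−2`, `k3`).

The degenerate combination `kd = 0` with zero concentration is rejected
rather than resolved, since 0/0 has no physical reading.

### Strain dependence

Strain scales up to two transition rates exponentially, with signs chosen
so that strain always depletes the post-power-stroke state: `k1` and `k2`
fall with `xB`, `k−1` rises with `xB`, `k−2` and `k3` rise with
`xC − xC0`.  Strain on `k−3` is excluded (the baseline rate is negligible,
`k−3 = 0` by default, though the equations carry it in full).  Because all
five exponentials equal one at the steady-state strains, the steady state
is provably independent of the strain sensitivities —
`steady_state_invariance_check()` verifies this, and it is why steady
stresses can be computed in closed form by the King–Altman rule.

## Linearisation

The complex modulus is obtained by Taylor-expanding the four state ODEs
about the steady state and solving `(jωI − J) X = b(jω)` for a unit
normalised-length input.  One generic complex solve covers all 64
permutations (`transfer_functions()`); the strain rows of `J` are pure
relaxations, so the system is block-triangular and the hot path
(`complex_modulus_linear()`) evaluates the same system through vectorised
closed forms, asserted equal to the generic solve to 10⁻¹².  All analytic
partials are locked against central finite differences of the nonlinear
right-hand side (step 10⁻⁷, relative tolerance 10⁻⁶) for every
permutation.

Two notational ambiguities in the printed closed forms were resolved by
re-derivation from the ODEs: the relaxation rate of `xC` under
rapid-equilibrium ATP carries the factor `ϕx` (consistent with its
companion expressions), and the symbol `C0` in the static-modulus formula
denotes the King–Altman *fraction*, whereas the state-variable steady
state is that fraction scaled by the availability `Z(L)` — at the working
length 2.2 µm, `Z ≈ 0.83`, and only the scaled reading reproduces the
measured steady stresses.

Two conventions are documented assumptions rather than derived facts:

* **Normalisation.**  Measured moduli are stress per fractional change of
  muscle length; the model's `dF/dL` is per µm of sarcomere length.  The
  package reports `L0 · dF/dL` with `L0 = 2.2` µm, i.e. muscle strain is
  taken equal to sarcomere strain.
* **Frequency grid.**  "17 frequencies log-spaced between 0.1 and 100 Hz
  (exclusive)" is realised as 18 log-spaced points from 0.1 to 100 Hz
  inclusive with the top point dropped (`frequency_grid()`), giving
  0.1 Hz as the first point and 66.6 Hz as the last.  Fitting always uses
  the dataset's own grid, so this choice only affects defaults.

## Time-domain validation

`integrate_model()` wraps deSolve's `lsoda` (relative tolerance 10⁻⁸ by
default, ≥ 200 output samples per sinusoid period).  The mean-strain
equations divide by `B` and `C`; the divisors are floored at 10⁻⁹ so the
right-hand side stays finite when a protocol crushes the occupancies, as
forced detachment does.  Occupancy admissibility during transients is a
soft expectation (trajectories may brush bounds at integrator noise
level), not an exception.

`complex_modulus_numeric()` reproduces the experimental estimator: drive
the full nonlinear model sinusoidally, discard the start-up transient, and
take the fundamental component of `FFT(F)/FFT(ΔL/L0)` over an integer
number of periods with no window (integer periods make leakage exactly
zero for the periodic part).  The discard is at least half the simulated
cycles and always at least eight time constants of the slowest linearised
eigenmode — at high frequencies many cycles fit inside one relaxation
time, and discarding "half of eight cycles" alone would bias the estimate.
A cycle-to-cycle RMS residual above 10⁻⁴ of the oscillation amplitude
raises a warning.  At 0.05 % amplitude the FFT modulus agrees with the
linearisation to well under 2 % for all 64 permutations; this first-order
consistency is the package's master validation of both code paths.

`force_redevelopment()` transiently scales the rates to detach
cross-bridges and then follows stress recovery at constant length.  The
printed protocol ("increasing detachment rates and decreasing attachment
rates 500-fold, isomerisation rates 10-fold, for 2 ms") does not enumerate
rates; the package maps detachment-direction rates `k−1, k3` ×500,
attachment-direction rates `k1, k−3` ÷500, and `k2, k−2` ×10.  The methods
text says 2 ms where a figure caption says 10 ms; 2 ms is the default and
the duration is a protocol parameter — the recovered stress is invariant
to it within 0.5 %, only the transient shape changes.  The summary reports
the recovered stress and a normalised redevelopment rate, the reciprocal
of the time to recover half of `F_final − F_min`.

## Fitting

The objective is the mean over metabolite conditions of the modulus RMSE
(elastic and viscous residuals pooled over `2 Nf` terms, unweighted — an
SEM-weighted variant exists but is off by default) plus a steady-stress
error with an exact dead zone of one SEM.  Parameter sets that break the
steady state return an infinite sentinel rather than an error.

Free-parameter boxes are not printed in the source material; the defaults
are rates 10⁻³–10³ s⁻¹ (or s⁻¹·mM⁻¹), `kd` 0.01–50 mM, strain
sensitivities 0–5000 µm⁻¹, `ϕx` 0.1–50, `ϕv` 10⁻³–10, `ϕl` 0–20,
stiffnesses 0–10⁴ kPa·µm⁻¹, all overridable.  The published `kdPi = 5.00`
mM sits suspiciously on a round value, so the default box keeps it well
interior.  The search runs in log₁₀ space because magnitudes span six
decades; boxes touching zero are floored at 10⁻⁶ of their upper bound,
indistinguishable from zero at the fitted scales.

The global search is a seeded constricted particle swarm (inertia 0.729,
acceleration coefficients 1.49445, reflecting bounds), written in-package
so the run is fully reproduced by its seed and settings.  A swarm alone
stalls outside the global basin on a substantial fraction of seeds for the
14-parameter permutations, so each run is polished by a bounded
Levenberg–Marquardt descent on the stacked residual vector followed by an
L-BFGS-B step on the exact objective, and `fit_study()` takes the best of
`n_restarts = 3` independent runs.  On noiseless five-condition synthetic
data this recovers all 14 generating parameters of permutation 16D to the
printed precision.  Default problem sizes — 60 particles × 300 iterations
per fit, 24 × 60 with a single restart per cell of the 64-permutation scan
— are desk-scale choices that complete a scan in a few minutes; they are
settings, not algorithmic constants.  Scan cells at reduced budget carry
optimiser noise of a few tenths of a per cent, which is why recovery is
judged by the family of equivalent permutations at the table minimum
rather than by a single cell.

## Synthetic data

`generate_study()` emulates the structure, not the raw waveforms, of the
trabecula measurements: five metabolite conditions (5/1, 1/1, 0.1/1, 5/0
and 5/5 mM ATP/Pi), 17 log-spaced frequencies, per-frequency means with
SEMs, and a steady stress per condition.  Noise is additive Gaussian,
independent across frequencies and between elastic and viscous components,
with standard deviation 3 % of the local modulus magnitude; the steady
stress receives 10 % noise.  Per-frequency SEM magnitudes are not reported
numerically in the source material, so these defaults are
order-of-magnitude emulations of the visible SEM-to-mean ratios, chosen
once.  A replicate mode (`n_replicates = 11`, matching the study's eleven
trabeculae) reports sample means and sample SEMs instead of nominal ones.

What the generator does *not* model: frequency-correlated errors, shared
per-muscle offsets (each condition is drawn independently), passive-modulus
subtraction artefacts, and any systematic model misspecification.  Passing
recovery tests on these data therefore demonstrate the identifiability and
correctness of the pipeline under the assumed error structure, not
robustness to the full error structure of real trabecula data —
reproducing the experimental RMSE table is out of reach without the
original measurements.  `degrade_study()` supports identifiability
experiments; e.g. single-condition data leave a dissociation constant
exactly unidentifiable (a compensated sweep of `kdATP` over a decade moves
the objective by nothing), while the five-condition design pins it.

## Known limitations

* No ADP sensitivity, no Ca²⁺ dynamics, no descending-limb mechanics, no
  spatially explicit or stochastic cross-bridge populations.
* The linearisation is only as good as the steady state: permutations
  driven to empty attached states (`B0` or `C0` = 0) have no defined
  frequency response and are reported as such.
* Strain-dependent rates must have nonzero, asymmetric derivatives at the
  reference strains to contribute to the linear response; a symmetric
  detachment component, if present in real muscle, is invisible to
  complex-modulus fitting.
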