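---
title: "Absolute cardiac T1 mapping from 3D PSIR: model, fit, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute cardiac T1 mapping from 3D PSIR}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psirt1)
```

## The problem

A phase-sensitive inversion recovery (PSIR) acquisition for late gadolinium
enhancement produces signed images on an arbitrary intensity scale. Scar is
visible as hyper-enhancement, but nothing absolute can be read off: window
settings, coil sensitivity and heart rate all move the numbers. The absolute
relaxation rate R1 = 1/T1, by contrast, is proportional to the local
gadolinium concentration and is comparable across time points, scanners and
patients. `psirt1` recovers T1 and M0 per voxel from the two readouts the
PSIR kernel already acquires, so quantification costs no extra scan time —
one breath-hold covers the ventricle.

## Magnetization model

One PSIR kernel spans two cardiac RR intervals and is parameterized by
`seq_params(rr_ms, t_inv_ms, tr_ms, flip_deg, tfe_factor, inversion_deg,
kernel_rr)`. The readout train has `tfe_factor` pulses of flip angle α every
TR, so its duration is T_acq = tfe_factor·TR (215 ms for the in-vivo
protocol: TR 9.4 ms, TFE 23). The longitudinal magnetization passes six
checkpoints:

* M_A, just after the inversion (modeled as Mz → Mz·cos θ_inv, transverse
  remnants assumed spoiled);
* M_B = relax(M_A → M0, T_inv, T1), the first measured point;
* M_C = relax(M_B → M0*, T_acq, T1*), end of the first train;
* M_D = relax(M_C → M0, RR − T_acq, T1), the second measured point;
* M_E = relax(M_D → M0*, T_acq, T1*);
* M_F = relax(M_E → M0, RR − T_inv − T_acq, T1), just before the next
  inversion,

with relax(m → m_∞, t, τ) = m_∞ + (m − m_∞)e^(−t/τ). A low–high k-space
order is assumed, so image intensity equals the magnetization at the *start*
of each train (M_B, M_D); no k-space filtering is modeled.

### Saturated readout: exact vs continuous asymptote

Sampling the discrete train just before each pulse gives the affine map
m → (cos α·e^(−TR/T1)) m + M0(1 − e^(−TR/T1)), whose iterates lie exactly on
an exponential with

* rate: 1/T1* = 1/T1 − ln(cos α)/TR — this is *exactly*
  −ln(cos α·e^(−TR/T1))/TR, no approximation;
* asymptote: M0* = M0(1 − E)/(1 − E cos α), E = e^(−TR/T1).

The classical continuous-limit asymptote M0* ≈ M0·T1*/T1 agrees to first
order in TR/T1 (0.419 vs 0.426 of M0 for T1 400 ms, TR 10 ms, α 15°) but
differs from the true pulse train by up to 1.6e-2·M0 in the steady-state
checkpoints at α = 25°. Since the package's correctness argument rests on
agreement with an independent pulse-by-pulse simulator to 1e-4·M0, the exact
discrete asymptote is used throughout; the continuous form remains available
as `apparent_relaxation(..., form = "continuous")`. Consequence worth
knowing: quantities that depend only on T1* (the Look-Locker rate
correction, the fitted T1 itself in the noiseless roundtrip) are identical
under either choice; only intermediate M_C/M_E values move.

### Steady state

With the kernel repeated every 2·RR, M_A = cos(θ_inv)·M_F closes the loop.
Each segment is affine in M_A, so M_F = a·M_A + b with 0 < a < 1 and the
fixed point M_A = b·cos θ/(1 − a·cos θ) is closed-form
(`steady_state_kernel`, with an iterative route retained for testing). Two
limits anchor it: single-shot (RR → ∞) gives M_A = −M0; any finite RR gives
|M_A| < M0.

## The two-point fit

`fit_two_point` implements the iterative inversion of (M_B, M_D):

1. initialize M0 = −M_A = M_D;
2. coarse T1 = T_inv / ln((M0 − M_A)/(M0 − M_B));
3. M_C through the train with (T1*, M0*) at the current T1;
4. M0 ← (M_D − M_C·E)/(1 − E), E = e^(−(RR − T_acq)/T1);
5. M_E, M_F through the remaining segments; M_A ← −M_F;
6. repeat from 2 until |ΔT1| < 0.01 ms (max 100 iterations).

The tolerance is far below measurement noise and the loop is a contraction
in practice (typically 5–15 iterations). T1 is clamped to [1, 5000] ms —
wide enough for pre- and post-Gd tissue and fluids — and clamped voxels are
flagged, not erased. When the step-2 logarithm's argument falls in (0, 1]
(the initialization M0 = M_D undersells M0 when T1 is long relative to RR),
T1 is set to the upper bound and iteration continues; the step-4 M0 update
then rescues the voxel. Arguments ≤ 0, M_D ≤ M_B, or M_D ≤ 0 mark the voxel
invalid without aborting a map fit — background noise does this routinely.
The fit is exactly scale-invariant: T1 depends only on intensity ratios, M0
carries the scale.

`fit_naive` solves the same two points under pure inversion recovery with
full recovery assumed (M_A = −M0, α = 0), by 1-D root finding. It exists to
quantify what ignoring saturation costs: at RR < 4–5·T1 it underestimates
T1 severely (e.g. 377 ms for a true 700 ms at 90 bpm).

`fit_look_locker` fits the continuous-readout steady state
M(t) = M0*(1 − (2/(1+e))e^(−t/T1*)), e = e^(−RR/T1*). The model has exactly
two free parameters: the amplitude is profiled out (the model is linear in
M0*) and the residual is minimized over T1* alone with `stats::optimize`,
which cannot diverge on a bounded interval; T1 then follows by inverting the
rate relation. The intercept is *not* a free third parameter — it is coupled
through e, matching the steady-state physics.

## Synthetic data: what the generator states, and what it does not

The digital phantom (`phantom_spec`) defaults to six discs of radius 8
voxels in a 72×48×1 grid with T1 = 228, 298, 411, 539, 638, 754 ms and
M0 = 1 — the agarose/Gd reference ladder spanning the post-contrast cardiac
range. Noise is additive Gaussian on both *signed* volumes (the
phase-corrected PSIR reconstruction makes real-channel noise Gaussian, not
Rician), default σ = 0.005·M0 (0.5 %), i.e. SNR ≈ 200 at M0 — a benign,
high-SNR 1.5 T regime. The arrhythmia Monte Carlo jitters every RR interval
independently and uniformly within ±5 % ("range" suggesting bounded
support), simulates pulse by pulse through 20 burn-in kernels (doubling the
burn-in changes the error estimates by less than their Monte-Carlo noise),
samples one kernel, and fits with the *nominal* RR — exactly the mismatch an
arrhythmic patient inflicts on the scanner. Error is reported as the
standard deviation of fitted T1 across replicates in percent of truth
(`pct_sd`); the mean bias is reported separately and stays at the fit
tolerance floor.

Not emulated: B1 inhomogeneity and slice-profile flip-angle errors, T2/T2*
decay and echo-time effects, partial volume and multi-exponential voxels,
fat–water chemical shift, Gibbs ringing, motion. A green phantom test
therefore establishes the *fit's* correctness against the stated physics,
not scanner-grade accuracy; the paper-reported empirical deviations at high
flip angle × long T1 are scanner effects outside this model, which is why
the noiseless sweeps here are flat by construction.

## Synthesis and null times

`synthesize_ir_tfe` evaluates the one-RR kernel steady state (inversion
every RR, M_D = M_E collapsed away) at each voxel's (T1, M0) and emits the
magnetization at readout start — signed, or rectified to magnitude as a
conventional IR-TFE displays it. `optimal_inversion_delay` bisects the
signed signal in T_inv to 0.01 ms (the signal is monotone in T_inv;
bisection is derivative-free and robust). The +20 ms scanner-workflow
compensation is an explicit `offset_ms` argument, not hard-coded physics.
Two non-obvious behaviors the tests pin down:

* The null time is far from T1·ln 2 (268 vs 347 ms for T1 = 500 ms under
  the IR-TFE protocol) and the textbook value is recovered only as α → 0,
  RR → ∞.
* A Look-Locker null must not be transferred to a PSIR (or IR-TFE)
  acquisition: for T1 = 400 ms at 60 bpm the LL steady state crosses zero at
  116 ms, the PSIR at 253 ms. The two coincide only in the joint limit
  α → 0 *and* RR ≫ T1 — vanishing flip alone is not enough, because the two
  sequences also differ in inversion period (RR vs 2·RR).

## Imperfect inversion: a documented discrepancy

Feeding the fit noiseless steady-state data generated with a 162° inversion
(10 % angle reduction, Mz → Mz·cos θ) produces an *under*estimation of T1
that grows with T1: −1.7 % at 200 ms to −7.6 % at 800 ms under the in-vivo
protocol. An independent exhaustive least-squares inversion of the same data
under the 180° model lands on identical T1 values, and the single-shot limit
can be worked by hand to the same sign: a shallower inversion looks like
faster recovery, hence a shorter T1. The source literature states the
opposite sign (an overestimation of 2–3 % across 200–800 ms); within this
forward model the published magnitude is reproduced only near the short-T1
end and the published sign is not reproduced at all. The acceptance suite
asserts the published claim verbatim and is expected to stay red on this one
criterion; the unit tests assert the computed behavior (sign, growth with
T1, vanishing at 180°, monotonicity in the angle).

## Numerical choices

* Times in ms throughout; R1 reported as 1000/T1 in s⁻¹.
* Steady state via the affine closed form; the fixed-point iteration is kept
  only as a test oracle (agreement to 1e-9).
* Fit convergence |ΔT1| < 0.01 ms, max 100 iterations; bounds [1, 5000] ms,
  clamp-and-flag.
* Bisection tolerances 0.01 ms for null times. The residual signal at a
  returned null is then ~1e-5·M0 (slope ≈ 2e-3·M0/ms), which is what the
  tests assert; demanding 1e-8·M0 would need a 1e-5 ms tolerance.
* Degenerate timing t_inv = 0 with T_acq = RR is allowed (non-strict
  inequalities) — it is the continuous-acquisition configuration whose
  two-RR steady state must, and does, reduce to the Look-Locker closed form.
* All stochastic components accept a single integer seed; the same seed
  reproduces volumes bit for bit.

## Known limitations

Mono-exponential T1 only; no B1/slice-profile correction (flip angle taken
as nominal); no Rician/magnitude noise model; no DICOM input (NIfTI-1 only;
the built-in reader covers single-file .nii/.nii.gz with the common
datatypes); the SNR comparison between IR-TFE and PSIR is the idealized
equal-geometry, equal-scan-time √2 argument, not a full sequence-efficiency
model.
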