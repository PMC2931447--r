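# psirt1 — absolute T1 quantification from 3D phase-sensitive inversion recovery

`psirt1` turns the two readouts of a 3D PSIR (phase-sensitive inversion
recovery) cardiac acquisition into absolute voxelwise T1 / R1 maps. PSIR is
the workhorse sequence for late gadolinium enhancement (LGE) imaging of
myocardial fibrosis, but its images are arbitrarily scaled: they show *that*
tissues differ in T1, not *by how much*. Because the PSIR kernel acquires
two signed images per 2·RR — one at inversion delay T_inv and one a full RR
later — those two points are enough to recover T1 and M0 absolutely, *if*
the saturation of the magnetization by the readout trains and the multi-shot
steady state are modeled. That model and its inversion are what this package
implements, for cardiologists/physicists working on quantitative LGE and for
method developers who need a controlled in-silico testbed.

## The model

Longitudinal magnetization during one 2·RR PSIR kernel passes six
checkpoints M_A…M_F: inversion → free relaxation over T_inv (M_A→M_B) →
first readout train (M_B→M_C) → free relaxation (M_C→M_D, duration
RR−T_acq) → second readout train (M_D→M_E) → free relaxation to the next
inversion (M_E→M_F). Every segment is an exponential approach
m(t) = m_∞ + (m_0 − m_∞)·e^(−t/τ). During a spoiled readout train of flip
angle α repeated every TR the effective parameters are

    1/T1* = 1/T1 − ln(cos α)/TR
    M0*   = M0 (1 − E)/(1 − E cos α),   E = e^(−TR/T1)

(the exact fixed point of the discrete pulse train; the familiar
M0* ≈ M0·T1*/T1 is its first-order approximation). In the multi-shot steady
state M_A = −M_F with |M_A| < M0; since each segment is affine in M_A the
steady state is available in closed form. T1 and M0 follow from the measured
pair (M_B, M_D) by the iterative two-point fit: initialize M0 = −M_A = M_D,
then cycle coarse-T1 (from the T_inv segment), M_C (through the train),
a refreshed M0 (from the inter-readout segment), and a refreshed M_A, until
T1 settles. A Look-Locker fit (continuous readout, inversion every RR) and a
"naive" pure-IR fit (which demonstrates the severe T1 underestimation you
get when saturation is ignored at clinical heart rates) are included, as is
synthesis of conventional IR-TFE/LGE images from the fitted maps at any
inversion delay.

Everything is validated against a discrete pulse-by-pulse simulator that
never uses the aggregate (T1*, M0*) closed form, plus a digital phantom with
the six reference tissues (T1 = 228, 298, 411, 539, 638, 754 ms), an
arrhythmia Monte Carlo (uniform ±5% per-interval RR jitter), and robustness
sweeps over flip angle, inversion delay and inversion-pulse imperfection.

## Worked example

```r
library(psirt1)
sq <- seq_params(rr_ms = 1000, t_inv_ms = 300, tr_ms = 9.4,
                 flip_deg = 15, tfe_factor = 23)     # T_acq = 216.2 ms
ph <- generate_phantom_volumes(phantom_spec(noise_sigma = 0.005, seed = 42), sq)
pm <- fit_map(ph$volume_b, ph$volume_d, sq, mask = ph$truth$mask)
pm
#> <parameter_map> 72x48x1 voxels, 1182 valid, 1182 converged
#>   T1 range 223.1 - 795.9 ms
sapply(1:6, function(i) median(pm$t1[ph$label == i], na.rm = TRUE))
#> true   228.0 298.0 411.0 539.0 638.0 754.0
#> fitted 228.3 298.1 411.1 538.8 637.4 753.1
```

With 0.5 % Gaussian noise on the signed volumes, every region median lands
within 0.2 ms–1 ms (≤ 0.15 %) of its ground truth. Choosing the inversion
delay that nulls healthy myocardium (T1 ≈ 500 ms post-Gd) in a synthesized
IR-TFE:

```r
optimal_inversion_delay(500, seq_params(rr_ms = 1000, tr_ms = 4.4,
                                        flip_deg = 18, tfe_factor = 43,
                                        kernel_rr = 1))
#> 268.2   # ms -- far from the textbook T1*ln2 = 346.6 ms, because of
#>         # readout saturation and the every-RR steady state
```

Arrhythmia sensitivity (1000 replicates per cell, ±5 % RR jitter, fitted
with the nominal RR; `pct_sd` = sd of fitted T1 as % of truth):

```r
arrhythmia_monte_carlo(c(300, 500, 700), c(60, 90),
                       arrhythmia_config(n_replicates = 1000, seed = 1),
                       seq_params(rr_ms = 1000, t_inv_ms = 300, tr_ms = 9.4,
                                  flip_deg = 18, tfe_factor = 23))
#>   t1_true_ms hr_bpm mean_t1_ms sd_t1_ms pct_sd
#> 1        300     60     299.92     2.05   0.68
#> 2        300     90     299.52     6.52   2.17
#> 3        500     60     500.01     8.75   1.75
#> 4        500     90     499.26    19.59   3.92
#> 5        700     60     699.13    21.33   3.05
#> 6        700     90     701.58    40.40   5.77
```

## Command line

```sh
exec/psirt1 phantom --out-prefix ph --seed 7 --flip 15 --tr 9.4 --tfe 23 \
            --t-inv 300 --rr 1000
exec/psirt1 fit --volume-b ph_b.nii.gz --volume-d ph_d.nii.gz \
            --out-prefix map --flip 15 --tr 9.4 --tfe 23 --t-inv 300 --rr 1000
exec/psirt1 null-time --t1-null 500 --rr 1000 --tr 4.4 --flip 18 --tfe 43
```

Subcommands: `fit`, `synth`, `null-time`, `phantom`, `mc-arrhythmia`,
`sweep`, `ll-fit`; run `exec/psirt1 --help` for all flags. Sequence
parameters may also come from a flat `key: value` config file (`--config`);
flags override it.

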