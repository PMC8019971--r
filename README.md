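# t2compart

Multicomponent T2 relaxometry for multi-echo spin-echo MRI: voxelwise T2
spectra, water-pool maps, and hyper-T2 lesion analysis.

## The problem

A 32-echo CPMG/GraSE acquisition (TE = 10, 20, ..., 320 ms) samples each
voxel's transverse decay. That decay is a mixture: water trapped in myelin
bilayers (T2 ≲ 40 ms), intra/extracellular water (IEw, 40–250 ms), and
cerebrospinal/free fluid (T2 > 250 ms). Decomposing it gives quantitative
maps that conventional FLAIR contrast cannot: in lower-grade glioma
patients, the IEw weighted-T2 map shows peri-tumoral alterations extending
*beyond* the FLAIR hyper-intense region (a T2/FLAIR "mismatch"), detecting
elevations of the IEw T2 peak as small as roughly 20 ms.

`t2compart` implements that analysis chain for researchers in quantitative
MRI and radiation oncology imaging:

1. **Forward model** — extended phase graph (EPG) echo amplitudes with
   stimulated-echo contamination when the refocusing flip angle deviates
   from 180°; at 180° exactly `exp(-TE/T2)`.
2. **Inversion** — per voxel, solve

   min ‖A(α)·x − y‖² + μ‖D₂x‖²,  x ≥ 0

   on 200 log-spaced T2 nodes over 1–3000 ms: non-negative least squares
   (Lawson–Hanson, compiled) with a minimum-curvature (second-difference)
   penalty whose weight μ is set per voxel by the discrepancy principle
   (data misfit ≤ 1.02 × the unregularized misfit), jointly estimating the
   refocusing angle α by a coarse-grid search with quadratic refinement.
3. **Compartment maps** — pool fractions and amplitude-weighted T2 per pool,
   assembled into congruent 3D volumes (NIfTI in/out) after 3D Gaussian
   pre-smoothing (sd 1.5 voxels) of each echo volume.
4. **Hyper-T2 analysis** — kernel-density T2 distributions per ROI, the
   inside/outside-GTV intersection threshold, strict-threshold segmentation
   with volumetry in ml, FLAIR-mismatch reporting (exclusive volumes, Dice),
   and mode/skewness statistics.
5. **Synthetic phantoms** — multi-echo volumes with known three-pool truth,
   a lesion/FLAIR-core mismatch geometry, a spatially varying flip angle and
   Rician noise, so the whole chain is testable without any acquisition.

## Worked example

```r
library(t2compart)

acq <- acq_params()                      # 32 echoes, TE 10..320 ms

# one white-matter-like voxel, imperfect refocusing, magnitude noise
model <- tissue_model()                  # 0.12 @ 20 ms, 0.80 @ 80 ms, 0.08 @ 1000 ms
y <- voxel_signal(model, flip = 165, acq = acq)
y <- add_rician_noise(y, snr = 200, seed = 1)

spec <- fit_echo_train(y, acq)
spec
#> <t2_spectrum> 200 nodes, flip 163.8 deg (fitted), mu 19, misfit 0.02123, total amplitude 1.044

glance(spec)
#> # A tibble: 1 × 10
#>   flip_angle    mu residual_norm myelin_fraction iew_fraction csf_fraction
#>        <dbl> <dbl>         <dbl>           <dbl>        <dbl>        <dbl>
#> 1       164.  19.0        0.0212           0.123        0.826       0.0502
#> # i 4 more variables: myelin_t2 <dbl>, iew_t2 <dbl>, csf_t2 <dbl>,
#> #   total_amplitude <dbl>
```

The fitted flip angle (163.8°) recovers the simulated 165°, and the pool
fractions (0.123 / 0.826 / 0.050) recover the generating model's
0.12 / 0.80 / 0.08; `iew_t2` is the voxel's IEw weighted T2 in ms — the
map value used everywhere downstream. Batches of voxels go through the same
fit in long format:

```r
trains <- phantom_voxels(5, model, flip = 165, snr = 200, acq = acq, seed = 2)
fit_voxels(trains, acq)
#> # A tibble: 5 × 11
#>   voxel flip_angle      mu residual_norm myelin_fraction iew_fraction ...
#> 1     1       170.  95.7          0.0278          0.0925        0.855
#> 2     2       164. 101.           0.0250          0.123         0.827
#> ...
```

Whole volumes run through `run_pipeline()`; the mismatch analysis chains the
map into `roi_distribution()` → `find_threshold()` → `segment_hyper_t2()` →
`mismatch_report()`:

```r
ph  <- make_phantom(phantom_spec(snr = 200, seed = 11))    # 24 x 24 x 12, lesion +30 ms
ms  <- run_pipeline(ph$echoes, ph$masks$brain, pipeline_config())
iew <- ms$maps$iew_t2
thr <- find_threshold(roi_distribution(iew, ph$masks$gtv),
                      roi_distribution(iew, ph$masks$brain & !ph$masks$gtv))
seg <- segment_hyper_t2(iew, ph$masks$ctv, thr, prod(ms$voxel_size) / 1000)
mismatch_report(seg, ph$masks$flair)
```

`autoplot()` works on fitted spectra and ROI distributions; `plot_map()`
renders map slices.

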