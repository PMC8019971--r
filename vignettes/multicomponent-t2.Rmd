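---
title: "Multicomponent T2 relaxometry: model, inversion and downstream analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicomponent T2 relaxometry: model, inversion and downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and its model

A multi-echo spin-echo (CPMG / GraSE) acquisition samples the transverse
decay of each voxel at 32 equally spaced echo times, TE = 10, 20, ..., 320 ms
(TR = 1000 ms). Brain water is not a single pool: water trapped between
myelin bilayers relaxes fast (T2 roughly 10-40 ms), intra/extracellular
water (IEw) relaxes at intermediate rates (roughly 60-140 ms in healthy and
perilesional tissue), and cerebrospinal/free fluid relaxes slowly
(T2 > 250 ms). The voxel signal is modeled as a non-negative superposition

\[ y(\mathrm{TE}_k) \;=\; \sum_j x_j \, a_k(T_{2,j}, \alpha), \qquad x_j \ge 0, \]

over a grid of 200 logarithmically spaced T2 values between 1 and 3000 ms.
The kernel \(a_k\) is **not** a pure exponential: real refocusing pulses
deviate from 180 degrees (B1 inhomogeneity), so part of the magnetization is
stored longitudinally and returns at later echoes as stimulated echoes. The
package computes \(a_k(T_2, \alpha)\) with the extended phase graph (EPG)
recursion: per half echo spacing, relaxation and one unit of crusher
dephasing; per pulse, mixing of transverse configuration states \(F(k)\)
with their conjugate counterparts and the longitudinal states \(Z(k)\)
(rotation about y, CPMG phase). States are truncated at order
`n_echoes + 1`, which cannot affect any echo inside the train. At
\(\alpha = 180^\circ\) the recursion collapses exactly to
\(\exp(-\mathrm{TE}/T_2)\); the test suite verifies the general case against
an independent isochromat (Bloch) simulation with 2001 spins.

Two fixed model constants deserve mention:

* **T1** is set to 1000 ms for every basis column (`acq_params(t1 =)`). The
  echo train ends at 320 ms, where the influence of T1 on stimulated-echo
  weights is weak; fits over this range are insensitive to the exact value.
* **T1 regrowth during the train is neglected** in both the EPG model and
  the isochromat oracle. Recovery feeds back into echoes only through
  subsequent pulses and is of order TE/T1 per interval; consistent treatment
  in model and oracle keeps the comparison honest.

Slice-profile effects are not modeled beyond a single effective flip angle
per voxel, matching how the per-voxel B1 correction treats them.

## Inversion: regularized NNLS with flip-angle estimation

`nnls_fit()` solves the convex problem
\(\min_x \lVert A x - y\rVert_2,\ x \ge 0\) with a Lawson-Hanson active-set
solver (compiled; expressed on the normal equations so that the regularized
path below can reuse cached Gram matrices and warm-started active sets).

`regularized_fit()` adds a minimum-curvature penalty,
\(\min_x \lVert A x - y \rVert^2 + \mu \lVert D_2 x \rVert^2\), where
\(D_2\) is the second-difference operator on the log-T2 grid **with
zero-padded boundaries**: the spectrum is treated as vanishing outside
[1, 3000] ms, so the operator carries boundary rows. This matters. Without
them, a linear ramp of amplitude running into a grid edge has exactly zero
curvature, and the edge nodes — whose T2 is far below the first echo time
and therefore almost invisible to the data — can accumulate arbitrarily
large, unpenalized amplitude.

The weight \(\mu\) is chosen per voxel by the discrepancy principle: the
largest \(\mu\) whose *data* misfit (residual 2-norm) does not exceed
`misfit_inflation` (default 1.02) times the unregularized misfit, located by
bracketing (factor-of-8 steps from \(10^{-3}\)) followed by 8 bisection
steps in \(\log \mu\). The selection is scale invariant because the whole
problem is scale equivariant in \(y\). With `misfit_inflation = 1` the
output equals the unregularized fit; for noiseless synthetic input the
tolerated misfit is essentially zero and \(\mu \to 0\), which is the correct
limiting behaviour.

`fit_flip_angle()` estimates the refocusing angle by scanning the
unregularized NNLS misfit over a coarse 1-degree grid on [120, 180],
refining the minimizer by quadratic interpolation through the best node and
its neighbours (clamped to one step, rounded to 0.1 degree), and finally
running the regularized fit at that angle. Ties resolve to the largest
angle; an all-flat misfit profile (pure noise) yields 180 degrees and a
`flat_misfit` flag. Two design points:

* The angle is estimated on the **unregularized** misfit — it is cheaper and
  avoids any bias of the curvature penalty on the angle.
* The search basis excludes T2 nodes below `flip_search_t2_min` (default
  15 ms, about 1.5 times the echo spacing). Components with T2 well below
  the first TE reach the data only through the earliest echoes, exactly
  where flip-angle error expresses itself; left in the search basis they
  make the misfit-versus-angle curve nearly flat and the joint problem
  degenerate, with a spurious solution branch that replaces about one degree
  of angle error by a large ultra-short-T2 component (myelin-water fractions
  of 0.7-0.9 in simulations at SNR 200). The **final** spectrum is always
  fitted on the full 1-3000 ms grid.

With both choices, 500-voxel simulations at SNR 200 (two pools, myelin water
fraction 0.15, IEw T2 85 ms, flip 150 degrees) recover the myelin water
fraction to within 0.03, the IEw weighted T2 to within 5 ms, and the flip
angle to within 5 degrees — the suite's parameter-recovery test.

## Compartments and maps

`partition_spectrum()` labels grid nodes: T2 below 40 ms is myelin water,
40-250 ms is intra/extracellular water, above 250 ms is fluid. A node
exactly at 40 or 250 ms belongs to the IEw pool (the default log grid has no
such node; the convention matters only for custom grids). Per pool it
reports the amplitude fraction and the amplitude-weighted **arithmetic**
mean T2; the geometric mean, common elsewhere in the myelin-water
literature, is available via `geometric_t2 = TRUE`. The myelin and fluid
weighted T2 maps are produced but are intrinsically unreliable: few echoes
fall below 40 ms, and the train ends at 320 ms, far short of fluid T2s. The
IEw weighted T2 map is the analysis readout.

`run_pipeline()` smooths each echo volume with a normalized 3D Gaussian
kernel (sd 1.5 voxels by default, reflected boundaries), fits every in-mask
voxel, and assembles eight congruent maps (three fractions, three weighted
T2s, flip angle, residual norm). The smoothing standard deviation is
interpreted in voxels of the acquired grid — a configurable, logged
assumption. Voxels whose first-echo magnitude falls below 5 times the
estimated background noise (Rayleigh-corrected mean of out-of-mask
first-echo magnitudes) are skipped and remain NaN; with no out-of-mask
voxels nothing is skipped. The pipeline is deterministic: identical inputs
and configuration give bit-identical maps, independent of voxel order.

## Downstream analysis: threshold, segmentation, mismatch, ROI statistics

The hyper-T2 analysis mirrors how quantitative IEw T2 maps are compared with
FLAIR hyper-intensity:

1. `roi_distribution()` estimates the normalized T2 distribution of the IEw
   map inside a mask by Gaussian KDE (Silverman bandwidth by default,
   configurable) on a regular support over [40, 250] ms, renormalized to
   unit trapezoidal integral. At least 30 finite voxels are required. The
   automatic bandwidth is floored at one local step of the spectral grid
   (4% of the sample median): map values are quantized on the 200-node log
   grid, so Silverman's rule collapses on nearly constant ROIs — e.g.
   heavily smoothed, high-SNR synthetic data — and would turn the density
   into a spike sharper than anything the map can resolve, pushing the
   intersection threshold against the narrow peak instead of between the
   class means. An explicit `bandwidth` bypasses the floor.
2. `find_threshold()` intersects the distribution of voxels inside the tumor
   volume (GTV) with that of voxels outside it: the crossing of the density
   difference between the two modes, linearly interpolated; with several
   crossings the one nearest the inter-mode midpoint is used (with a
   warning). KDE makes this intersection well defined where raw histograms
   would not be.
3. `segment_hyper_t2()` selects CTV voxels with IEw T2 **strictly greater**
   than the threshold (NaN never selected) and reports the volume in ml. A
   single global threshold per subject is supported by passing the same
   value to later time points.
4. `mismatch_report()` quantifies segmentation-versus-FLAIR overlap:
   exclusive volumes, overlap and Dice. Elevated quantitative T2 extending
   beyond the FLAIR-positive region appears as `t2_only_ml > 0` with the
   FLAIR mask contained in the segmentation.
5. `distribution_stats()` reports the density mode and the adjusted
   Fisher-Pearson sample skewness — the "shifted mode, positive skew"
   signature of perilesional alteration.

## The synthetic phantom

`make_phantom()` generates the statistical structure the analysis assumes,
with known truth: a 24 x 24 x 12 volume of 2.5 mm voxels (small enough that
the full pipeline runs in minutes on one CPU; configurable), three-pool
white-matter tissue (0.12 @ 20 ms / 0.80 @ 80 ms / 0.08 @ 1000 ms), a
spherical lesion (radius 5 voxels) whose IEw T2 is elevated by 30 ms to
110 ms — inside the 70-140 ms band where pathological IEw peaks sit — with
reduced myelin fraction (0.06 / 0.86 / 0.08), a FLAIR-positive core of
radius 3 strictly inside the lesion (the GTV), so the lesion's outer shell
is a T2/FLAIR mismatch, a CTV sphere of radius 8, a contralateral reference
ROI, a refocusing flip angle varying linearly from 180 to 160 degrees along
x (to exercise the per-voxel B1 fit), and Rician magnitude noise
\(\sqrt{(s+g_1)^2+g_2^2}\) with \(\sigma\) set by the tissue first-echo
amplitude over the SNR. TR-driven T1 saturation is folded into the constant
per-pool proton density, since TR is fixed in-protocol. Default SNR is 200;
the sensitivity analysis uses 100 — acquisition SNR is a documented
assumption, not a measured quantity.

What the phantom does **not** emulate: anatomy and partial-volume mixtures of
tissue classes, spatially correlated (multi-coil) noise, B1 fields that vary
in more than one direction, imperfect FLAIR-to-T2 registration, and any
FLAIR signal model (FLAIR positivity is a mask, which is also how it enters
the real analysis). Tests passing on the phantom therefore validate the
estimator chain — not robustness to those real-data effects.

## Sensitivity analysis

`sensitivity_sweep()` asks how small an IEw T2 elevation the voxelwise fit
can detect: per elevation in {5, 10, 15, 20, 30, 40} ms, 200 baseline and
200 lesion voxels are simulated at first-echo SNR 100 and refocusing flip
170 degrees (the midpoint of the phantom's default B1 range; chosen once),
fitted with the full pipeline, and classified by the baseline IEw-T2
distribution's 95th percentile — a 5% false-positive operating point.
Baseline voxels are drawn fresh per condition. `detection_limit()` returns
the smallest elevation reaching 90% sensitivity. `scripts/acceptance.R`
reruns exactly this sweep from a command-line seed.

## Numerical choices and edge cases

* NNLS tolerance scales with \(\lVert A^\top y\rVert_\infty\), preserving
  scale equivariance down to zero signal (which returns a zero spectrum, not
  an error).
* Degenerate subproblems in the active-set solver fall back to a
  pseudo-inverse solve; a stalled iteration drops the most negative
  coefficient rather than cycling.
* The discrepancy bracket gives up after 60 expansions and falls back to
  \(\mu = 0\) with a warning.
* `find_threshold()` errors when the modes coincide or no crossing exists
  between them; `roi_distribution()` errors below 30 finite voxels;
  `segment_hyper_t2()` rejects thresholds outside (40, 250) ms and empty
  CTVs.
* Problem sizes in the test suite (80-500 Monte-Carlo voxels, a 24 x 24 x 12
  phantom, 2400 fitted voxels in the sensitivity sweep) are the package's
  chosen desk-scale study conditions.

## Known limitations

* The myelin-water fraction is the least stable output of the joint
  (spectrum, flip angle) fit; its residual scatter at SNR 200 is large
  (about 0.08 sd per voxel) even though its mean is accurate. The IEw
  weighted T2 — the primary readout — is far more stable.
* Quantitative agreement with any specific external tool's spectra is not
  claimed: regularization operators and weight-selection rules differ
  between implementations. The package's claims are about recovery of the
  underlying physical quantities, which the oracle-based tests check.
* Magnitude fitting uses unweighted least squares (a Gaussian approximation);
  Rician bias is negligible at the SNRs simulated here and is handled only in
  the simulator.
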