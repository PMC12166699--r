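---
title: "Free-running 5D whole-heart CMR at desk scale: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-running 5D whole-heart CMR at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(freerun5d)
```

## The method

Free-running whole-heart CMR collects 3D radial k-space continuously,
without ECG triggering, breath-holds, or navigators.  Motion is handled
retrospectively: a superior-inferior (SI) projection readout, acquired at
the start of every interleave, tracks the head-foot position of the heart
and diaphragm over time; principal component analysis of the stacked SI
projections yields a cardiac and a respiratory self-gating signal; every
readout is then sorted into one of `n_cardiac x n_resp` motion states, and
a single compressed-sensing reconstruction recovers one 3D image per state
-- a five-dimensional (x, y, z, cardiac phase, respiratory amplitude)
image.  Ventricular volumes, ejection fraction (EF), and the left atrial
volume index are measured on reformatted thick slabs of the end-expiration
frames.

This package implements the full chain at desk scale -- trajectory design
arithmetic, a dynamic numerical heart phantom with analytic ground truth,
the k-space simulator, SI self-gating, binning, the motion-resolved
reconstruction, and the quantitative metrics -- so that every stage can be
validated against known truth on a single CPU in minutes.

## Acquisition design arithmetic

For a matrix size $N_p$ and $N_{im}$ motion-resolved images, the number of
radial lines that gives each image a fraction $U$ of the radial Nyquist
criterion is the smallest integer exceeding $(\pi/4) N_p^2 N_{im} U$.  At
the reference protocol ($N_p = 160$, $N_{im} = 80$, $U = 5\%$) this is
80,425 lines; divided into interleaves of 18 readouts (one SI readout
leading each interleave) the minimal interleave count by ceiling division
is 4,469.  Not every phyllotaxis interleave count yields a smooth,
eddy-current-friendly gradient ordering, so the final count is the
smallest *admissible* value at or above the minimum; the admissibility
predicate is injected (`select_admissible_interleaves()`), because the
smoothness criterion lives in scanner-specific prior work.  With the
replication predicate fixed to 4,529 interleaves the design reproduces the
reference protocol's 81,522 readouts, an SI readout every 106.92 ms (107 ms) at
TR = 5.94 ms, and a total acquisition of 484.2 s.  Two printed-value
discrepancies are worth noting for anyone comparing against the reference
protocol: the reference protocol reports 80425/18 as 4446 where ceiling
division gives 4469, and a total time of 7:50 min where 81,522 x 5.94 ms = 8:04; the
package follows the arithmetic and reports both.

The spiral phyllotaxis itself places point $n$ of $N$ at azimuth
$n \cdot 137.50776°$ (the golden angle) with $\cos\theta$ descending
linearly from the pole to the equator -- uniform solid-angle density on
the hemisphere, which suffices because spokes are full diameters.  Points
are regrouped into interleaves by stride, and the first readout of each
interleave is replaced by the +z SI direction.

## The synthetic heart and what it does (and does not) emulate

The phantom is a set of ellipsoids: a static torso background, an LV blood
pool inside a static epicardial shell, an RV blood pool, and an LA blood
pool.  Chambers are painted in a fixed order (static structures first),
so the shell provides the septum and atrioventricular wall, and the LV
blood pool -- painted last -- always has exactly its analytic ellipsoid
volume $(4/3)\pi abc$.  Intensities approximate bSSFP contrast: blood 4.0,
myocardium 1.0 (contrast ratio 4, the scale of breath-held cine imaging).

Choices that matter, with rationale:

* **Contraction.** Ventricular semi-axes shrink by a fraction $f$ through
  a raised-cosine rise and fall occupying 40% of the RR interval, with
  an **end-systolic plateau** (35% of the systolic window, ~130 ms at
  66 bpm) during which the
  volume holds its minimum.  The plateau models the isovolumic phases of
  the cardiac cycle; it is also what makes end-systolic volume measurable
  from finite-width cardiac bins, in vivo as here: without it, any
  trigger-anchored bin averages across an instantaneous trough and EF is
  systematically underestimated by construction (we measured an EF
  ceiling of 49% vs. an analytic 58% for a pointy waveform, with the
  reconstruction replaced by an oracle).  The analytic ejection fraction
  is $1-(1-f)^3$; the default $f = 0.25$ gives 57.8%, a healthy adult
  value consistent with reference cine cohorts.
* **Epicardial shell.** The shell is static: the endocardium moves inward
  at systole while the epicardial surface moves little, so the wall
  thickens -- and a myocardial reference region near the shell stays
  myocardium at every phase, which the volume measurement relies on.
* **Respiration.** A rigid head-foot translation of the heart chambers
  with an end-expiratory plateau (squared raised-cosine, default 8 mm,
  4 s period); the torso background stays still, as the chest wall does.
  No hysteresis, no through-plane deformation.
* **RR variability.** Multiplicative Gaussian jitter per beat (default
  3%, truncated at 3 sigma), drawn once from the phantom seed into a beat
  table, so the true beat times and phases of every readout are known
  exactly.
* **Noise.** Complex white Gaussian noise with
  $\sigma = \sigma_{ref}\sqrt{BW/401}$; the default $\sigma_{ref}$ is
  calibrated so the motion-averaged gridded image SNR at 401 Hz/px is
  about 56, the operating point reported for the reference low-field
  protocol (SNR 77/56/46/39 at 201/401/601/801 Hz/px, an inverse square
  root law that the simulator reproduces and the tests check).
* **What is not emulated.** Bloch dynamics, bSSFP banding and flow
  effects, T1/T2 relaxation, realistic torso anatomy, coil noise
  correlation, trajectory errors from eddy currents or gradient
  nonlinearity.  Passing tests demonstrate the pipeline's internal
  correctness and motion-recovery behaviour, not robustness to these
  physical effects.

The simulator renders frames at 32 quantized cardiac phases per beat
(about 28 ms at RR 909 ms, finer than the bin width) and applies the
respiratory shift exactly, per readout, as a k-space phase ramp on the
heart term of a static-background/moving-heart decomposition.  The
decomposition is exact for the painted frames because breathing chambers
are painted after static ones.

## Self-gating

The SI readouts are inverse-Fourier-transformed into head-foot projection
profiles, stacked (all coils) into a space x time matrix, and analysed by
PCA along the spatial dimension.  For each physiological band -- cardiac
0.7-3 Hz (42-180 bpm), respiratory 0.08-0.7 Hz (5-42 breaths/min) -- the
component with the largest *absolute* in-band spectral power is selected.
We deliberately rank by absolute power (component variance times in-band
fraction) rather than in-band fraction alone: small, noise-dominated
components can have a large in-band *fraction* by chance, while the
physiological components carry large absolute power; ranking by fraction
mis-selected harmonic components in our experiments.

Trigger detection estimates the fundamental heart rate from the
autocorrelation peak over the plausible RR range (robust against the
respiratory modulation sidebands at $f_{card} \pm f_{resp}$ that dominate
the raw periodogram), re-filters the cardiac signal to a narrow band
around the fundamental, and places one trigger per beat at the local
maxima, refined to sub-sample precision by quadratic interpolation --
important because the SI sampling interval (107 ms) exceeds the cardiac
bin width (50-72 ms).  Detected triggers sit at the systolic signal
maximum, a fixed latency after the true beat onset; accuracy statements
about binning are therefore made modulo that constant latency
(`gating_accuracy()` estimates and removes it).

Binning is trigger-anchored: bin $\lfloor (t - t_{trig})/w \rfloor$ with
$n_{bins} = \lfloor \mathrm{median(RR)}/w \rfloor$, readouts beyond the
last bin rejected, and whole beats rejected when their RR deviates more
than 20% from the median (an arrhythmia guard of our own design).
Respiratory bins are amplitude quantiles over accepted readouts,
populations equal within one; bin 1 is end expiration, the quantile where
the signal dwells longest and intra-bin displacement variance is
smallest, and the state used for all quantitative analysis.  An
alternative phase-normalized binning (fixed bin count per beat) is the
commonly preferred for arrhythmic subjects; we implement the literal
trigger-anchored variant as the default.

## Reconstruction

The motion-resolved image $m$ minimizes

$$\|W^{1/2}(FCm - s)\|_2^2 + \lambda_c\|\nabla_c m\|_1
  + \lambda_r\|\nabla_r m\|_1,$$

where $F$ is the (binned) non-uniform Fourier transform, $C$ the coil
sensitivities, $\nabla_c, \nabla_r$ non-periodic first-order differences
along the cardiac and respiratory bin dimensions, and $W$ the radial
density weights.  Three numerical choices deserve explanation:

* **Density-weighted data fidelity.** The radial sample density falls as
  $1/|k|^2$, so the unweighted normal operator $F^HF$ has a spectrum
  spanning several orders of magnitude: gradient iterations fit low
  frequencies first and, at practical iteration counts, either converge
  to a streaky minimum-norm solution (small $\lambda$) or let the TV term
  erase high-frequency detail long before the data term converges (large
  $\lambda$).  Weighting the fidelity by the density weights whitens the
  spectrum ($F^HWF \approx$ identity on the sampled band), after which
  the conjugate-gradient sub-problem converges in a few iterations and a
  single dimensionless $\lambda$ acts evenly across spatial frequencies.
  This is the standard formulation in radial compressed-sensing practice.
  On consistent (densely sampled, noiseless) data the weighting does not
  change the minimizer, which is what the operator-correctness tests
  exploit.
* **Normalization.** The data are scaled so the density-compensated
  adjoint image has maximum magnitude 1, and the weighted data term is
  divided by the operator norm of $F^HWF$ (five power iterations).  Both
  together make $\rho = 1$ and $\lambda$ values of order 0.005
  transferable across grid sizes and sample counts; 0.005 for both
  weights is the default operating point, with the qualitative behaviour
  of the reference weight sweep preserved: raising $\lambda_c$
  monotonically compresses cardiac temporal variation (motion blur),
  raising $\lambda_r$ merges respiratory states.
* **ADMM schedule and early stopping.** ADMM splits the two TV terms
  (soft thresholding with threshold $\lambda/2\rho$) and solves the
  quadratic sub-problem by warm-started CG.  The pipeline default is a
  deliberately short schedule (5 outer iterations, 2 inner CG steps),
  and the iteration budget is doing real regularization work: with a
  handful of coils and a few hundred spokes per bin the per-bin problem
  is strongly underdetermined, and iterating the data term to
  convergence *semiconverges* -- per-bin volumes drift monotonically
  toward a noise-fitting minimum-norm solution (we measured systolic
  volume inflating from 36 to 47 mL over 15 unregularized CG steps while
  the diastolic volume deflated from 81 to 75 mL).  Temporal TV slows
  but does not stop the drift at weights that preserve motion; raising
  the weight far enough to stop it (0.02 and above in the normalized
  convention) compresses the volume curve outright.  Early stopping of a
  warm-started iteration from the gridded initialisation is the field's
  standard resolution of this trade-off and is what the default
  schedule encodes; `recon_config()` exposes the full schedule for
  scenes with more data.  Stopping: relative objective change below
  `tolerance` (1e-4) or the iteration cap; an objective increase beyond
  10x the initial value raises a solver-failure error.  Empty bins carry
  no data term and are filled through the TV coupling.

Coil maps come from Hamming-windowed, density-compensated gridded images
of the motion-averaged data, divided by their root sum of squares --
smooth, dependency-free, and adequate for the smooth simulated coils
(median magnitude error < 10% against the simulator's true profiles in
the tests).  The window is specified as a fixed spatial resolution of 10
cycles across the FOV -- identical to a cut at 12.5% of the maximal
k-space radius on a 160-point matrix, and resolution-consistent on the
coarser desk-scale grids.  Density compensation is used
only there and for initialisation, never as a preconditioner of the final
answer: the converged solution is defined by the objective above.

The NUFFT is Kaiser-Bessel gridding (Beatty shape parameter) onto a
5-smooth oversampled grid with R's FFT; the spreading/interpolation
kernels are exact transposes, so the forward/adjoint pair passes the
inner-product test at machine precision independent of kernel accuracy.
Defaults (oversampling 1.5, width 4) give ~3e-3 relative accuracy --
ample below the undersampling artifact level; width 8 at oversampling 2
gives ~1e-7 and is used where tests need near-exact transforms.

## Measurement

Volumes are measured by a partial-volume-aware fractional sum over an
ellipsoidal region anchored on the LV: $\sum_R (I - I_{myo}) /
(I_{blood} - I_{myo})\, v_{vox}$, with the blood and myocardium reference
intensities taken from the image itself (a core region that is blood at
every phase; a band inside the myocardial wall at every phase).  The
unclamped sum is conserved under integral-preserving blur, which makes
the estimate accurate at 3.3 mm voxels (exact to < 1% on ideally
band-limited frames in the tests).  ED and ES are the volume extremes
across cardiac bins of the end-expiration state; EF follows.  Contrast
ratio, SNR and Laplacian-variance sharpness are measured on an 8 mm
short-axis reformat, matching how thick-slab cine slices are analysed;
the 3x3 Laplacian is the 4-neighbour kernel (8-neighbour by flag), and
all variances use the n-1 denominator.  The biplane area-length atrial
volume $8A_1A_2/(3\pi L_{min})$, indexed to the Du Bois body surface area
($0.007184\, w^{0.425} h^{0.725}$), is exact for spheres by construction
-- the tests assert it at machine precision.  Agreement between two
measurement series uses Bland-Altman bias and 95% limits of agreement
(bias $\pm 1.96$ sd), $R^2$ of the linear fit, and a two-sided paired
Wilcoxon signed-rank test, exact by enumeration over sign assignments
(midranks, zeros dropped) for up to 25 pairs.

## Desk-scale study conditions

The default study conditions (`pipeline_config()`, also the `"standard"`
fixture) are a 48-voxel isotropic grid over a 160 mm FOV (3.3 mm voxels),
45 s of free-running acquisition at TR 5.94 ms with 18 readouts per
interleave (7,560 readouts, 420 SI projections), heart rate 66 bpm with
3% RR jitter, 4 s / 8 mm respiration, 2 coils, 72 ms cardiac bins (12
bins at RR 909 ms) and 2 respiratory bins -- about 280 spokes per bin, a
per-bin undersampling factor near 7.  The `"tiny"` fixture (24-voxel
grid, 1 coil, 12 s) is a smoke-test scene; `"stress"` raises the RR
jitter to 5%.  These sizes keep a full simulate-gate-reconstruct-measure
cycle in minutes on one CPU while preserving the regime that matters
(undersampled bins coupled by TV).  Reformatting, metrics and agreement
statistics are independent of grid size.

## Known limitations

* The phantom's motion is affine per chamber (scaling + translation);
  there is no twisting, through-plane shear, or hysteresis, so the
  self-gating problem is easier than in vivo.
* Trigger-anchored binning leaves a constant trigger latency relative to
  true beat onset; bin indices are physiologic phases only up to that
  shift (the analysis accounts for it, and end-diastole/end-systole are
  identified from the volume curve, not from bin index).
* The reconstruction is dimensioned for desk-scale grids; no GPU path, no
  Toeplitz embedding, no parallel coil loop.
* Single-coil scenes carry no parallel-imaging information, and the coil
  maps of multi-coil scenes are estimated from motion-averaged data --
  accurate here because the simulated profiles are broad and smooth.
* The CS data fidelity is density-weighted least squares; with noisy data
  this is a (deliberate) preconditioning choice, not the maximum-likelihood
  weighting.
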