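# freerun5d

Fully self-gated, free-running **5D whole-heart cardiac MR** at desk
scale: 3D radial spiral-phyllotaxis trajectory design with interleaved
superior-inferior (SI) self-navigation readouts, a beating and breathing
numerical heart phantom with analytic ground truth, PCA self-gating,
cardiac/respiratory binning, motion-resolved compressed-sensing
reconstruction, and quantitative cardiac function analysis.

Free-running CMR acquires 3D radial k-space continuously — no ECG, no
breath-holds, no navigators. Motion is resolved retrospectively: the 1D
projection of an SI readout, repeated every interleave, tracks heart and
diaphragm position; PCA of the stacked projections yields cardiac and
respiratory self-gating signals; every readout is sorted into a
(cardiac, respiratory) bin; and one compressed-sensing problem

$$\hat m = \arg\min_m \|W^{1/2}(FCm - s)\|_2^2
  + \lambda_r\|\nabla_r m\|_1 + \lambda_c\|\nabla_c m\|_1$$

recovers a five-dimensional image $m(x, y, z, \text{cardiac},
\text{respiratory})$, where $F$ is the non-uniform FFT on each bin's
spokes, $C$ the coil sensitivities, $W$ radial density weights, and
$\nabla_c, \nabla_r$ first-order finite differences along the two motion
dimensions (ADMM, soft thresholding + conjugate gradients). Ventricular
volumes, ejection fraction, the biplane area-length left atrial volume
index with Du Bois BSA, contrast ratio, SNR, Laplacian-variance
sharpness, and Bland–Altman/Wilcoxon agreement statistics are measured
on the end-expiration frames.

The package is aimed at readers and developers of free-running CMR
methods who want every stage of the chain runnable, inspectable, and
testable against analytic truth on one CPU — not at reconstructing
scanner data.

## Worked example

```r
library(freerun5d)

# the acquisition-budget arithmetic of the reference protocol
nyquist_line_count(Np = 160, Nim = 80, Ufactor = 0.05)
#> [1] 80425
design <- acquisition_design(Nshots = 4529)   # readouts_per_shot 18, TR 5.94
design
#> Free-running acquisition design
#>   matrix 160^3, 80 motion-resolved images, 5% Nyquist per image
#>   4529 interleaves x 18 readouts = 81522 readouts, TR 5.94 ms
#>   SI interval 106.9 ms, scan time 484.2 s

# the standard desk-scale study: 48^3 grid, 2 coils, 45 s free-running
# acquisition, heart rate 66 bpm, 12 cardiac x 2 respiratory bins
report <- run_pipeline(fixture_config("standard", seed = 7))
report
#> 5D free-running pipeline report
#>   EF measured 55.8% (truth 57.8%, error -2.0 points)
#>   EDV 82.3 mL, ESV 36.4 mL; 12 cardiac x 2 respiratory bins
#>   median RR 908 ms, 94.3% readouts accepted
#>   CR 3.43, LAPV 0.00492, SNR 4.7
```

The first block reproduces the reference protocol's line budget (80,425 radial
lines for a 160³ matrix at 5% Nyquist per image across 80 images), the
interleave structure (4,529 interleaves × 18 readouts = 81,522
readouts), and the SI-navigator interval (107 ms at TR 5.94 ms). The
pipeline report shows the left-ventricular ejection fraction measured on
the reconstruction against the phantom's analytic value
($EF = 1-(1-f)^3$ for contraction fraction $f$), the end-diastolic and
end-systolic volumes from partial-volume-aware voxel counting in the
end-expiration state, the fraction of readouts accepted by the
self-gating chain, and blood–myocardium contrast ratio (CR), sharpness
(LAPV) and SNR measured on an 8 mm short-axis reformat.

Individual stages are exported — `generate_phyllotaxis()`,
`simulate_kspace()`, `extract_si_matrix()`, `derive_motion_signals()`,
`detect_triggers()`, `assign_bins()`, `estimate_sensitivities()`,
`reconstruct_5d()`, `reformat_slab()`, `lavi_biplane()`,
`agreement_stats()`, … — see the methods vignette
(`vignettes/freerun5d-methods.Rmd`) for the models, parameter meanings,
and the reasoning behind the numerical choices. A thin command-line
front end lives in `inst/scripts/freerun5d.R`.

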