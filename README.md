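# freerunfw

Simulation and analysis toolkit for **free-running chemical-shift-encoded
(CSE) cardiac MRI at 3T**: quantitative fat-water separation
(proton-density fat fraction, R2\*, B0 mapping) from multi-echo radial
acquisitions with gradient-chain (GIRF) trajectory correction and
motion-resolved compressed-sensing reconstruction.

## Who this is for

Researchers in quantitative MRI who want to

* study how echo-scheme design (monopolar vs bipolar readouts, echo count
  and spacing) determines PDFF/R2\* accuracy at 3T, through controlled
  in-silico experiments;
* prototype IDEAL-type fat-water estimators (variable projection over B0
  and R2\* with a spatially constrained field map) and quantify bias,
  precision and fat-water swap behaviour;
* model a gradient chain as a per-axis linear system (delays, mechanical
  resonances, bandwidth loss), simulate its thin-slice measurement,
  estimate the gradient impulse response function (GIRF), and correct
  3D radial spiral-phyllotaxis k-space trajectories;
* exercise a full free-running pipeline at desk scale: self-gating from
  superior-inferior projections, cardiac/respiratory binning, SVD coil
  compression, and ADMM total-variation compressed sensing.

Everything runs on synthetic data generated by the package; no scanner
data are needed.

## The core model

A voxel with water/fat magnitudes (W, F) produces the multi-echo signal

    y(t) = (W + F * sum_m alpha_m exp(i w_m t)) * exp(i phi0)
           * exp((i 2 pi f0 - R2*) t)

with a 10-peak subcutaneous fat spectrum (relative amplitudes alpha_m,
frequency offsets w_m at 2.89 T), off-resonance f0, shared decay R2\* and
common initial phase phi0. PDFF = 100 F/(W+F). The estimator solves for
(W, F, f0, R2\*) per voxel by variable projection: complex amplitudes are
projected out by linear least squares on a shared coarse (f0, R2\*) grid
(BLAS-batched over the whole volume, refined per voxel in C++), and a
neighborhood-median field-map constraint suppresses isolated fat-water
swaps.

## Worked example

Simulate the in-silico accuracy study at a reduced size (4 noise
repetitions instead of 100), fit it, and summarize:

```r
library(freerunfw)

grid <- silico_grid(n_reps = 4, snr = 10)        # PDFF 0:100%, f0 -200:200 Hz
vol  <- generate_silico_volume(grid, scheme_preset("bipolar3T"))
vol  <- add_complex_noise(normalize_volume(vol), snr = 10, seed = 42)
res  <- fit_volume(vol)
accuracy_report(grid, res)
#> <accuracy_report>
#>   mean PDFF bias:      +0.0610 %
#>   mean |PDFF error|:   2.3149 %
#>   mean R2* bias:       +0.0728 1/s
#>   max |R2* err| prof.: 11.73 1/s
#>   swap fraction:       0.0155
```

At SNR 10 the 13-echo bipolar scheme keeps the mean absolute PDFF error
near 2.3% with essentially zero bias; the same run with
`scheme_preset("monopolar3T")` gives ~4.3% with fat-water swaps
concentrated above 85% true PDFF — the echo-spacing argument in numbers
(the monopolar spacing, 1.96 ms, cannot undercut the 1.23 ms water-fat
in/out-of-phase delay at 2.89 T; the bipolar spacing, 1.07 ms, can):

```r
inphase_outphase_delay(default_fat_spectrum())
#> [1] 1.230948
```

Trajectory correction demo (static water phantom, bipolar readout through
a distorted gradient chain; even/odd-echo inconsistency with and without
GIRF-corrected trajectories):

```r
demo <- trajectory_artifact_demo()
c(nominal = demo$metric_nominal, corrected = demo$metric_corrected)
#>   nominal corrected
#> 0.08075322 0.06895297
```

A command-line interface wraps the main workflows
(`simulate`, `fit`, `girf`, `traj`, `recon-demo`, `report`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","freerunfw.R",package="freerunfw"))')" \
    simulate --scheme bipolar3T --snr 10 --seed 1 --out vol.nii.gz
```

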