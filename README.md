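# ecgidsp

Spatial-temporal conditioning and bipolar electrogram construction for
meshed unipolar potentials, as produced by electrocardiographic imaging
(ECGI).

ECGI reconstructs epicardial potentials at hundreds of mesh nodes at
once. Each node behaves like a **unipolar electrogram** (local activity
plus far field), but clinical electrophysiology — voltage mapping,
scar delineation, fragmentation grading — is defined on **bipolar
electrograms**, differences between two closely spaced electrodes.
`ecgidsp` is for signal-processing and electrophysiology researchers who
want to condition meshed potential fields and derive clinically shaped
bipolar signals and maps from them.

## What it computes

Given a triangle mesh (one-ring neighborhood η<sub>i</sub> per node) and
a potentials matrix v(s<sub>i</sub>, t), the package provides:

* **Preprocessing** under the additive model
  v<sub>m</sub> = v + N + B + R: cubic-spline baseline-wander removal
  (knots every T<sub>w</sub> seconds), zero-phase Butterworth low-pass
  filtering (9th-order design, 100 Hz, applied forward-backward), and
  envelope-based beat segmentation. Every stage returns both the cleaned
  signal and the removed residual, and the two always sum back to the
  input sample-exactly.
* **M-mode analysis**: time-space stacks along shortest edge-paths,
  their full 2-D spatial-temporal autocorrelation
  R<sub>x</sub>(τ, λ), marginal (purely temporal / purely spatial)
  slices, misadaptation diagnostics for the detrending window, and
  correlation-sign polarity alignment.
* **DSPOs** (digital signal processing operators) that pick, per node,
  the reference for the bipolar electrogram
  β(s<sub>i</sub>, t<sub>w</sub>) = v(s<sub>i</sub>, t<sub>w</sub>) −
  v(s<sub>k</sub>, t<sub>w</sub> − α): max/min neighbor amplitude
  (θ<sub>V</sub>, θ<sub>v</sub>), max/min distance (θ<sub>D</sub>,
  θ<sub>d</sub>), mean virtual reference (θ<sub>m</sub>), seeded random
  (θ<sub>r</sub>), the self-difference / delayed-reference family (FTD),
  and the delayed maximum-amplitude operator θ<sub>Vα</sub> whose
  default delay of 40 samples at 2048 Hz (0.0195 s ≈ 6 mm of wavefront
  travel at 0.3 m/s) restores catheter-like bipolar morphology.
* **Clinical indices**: peak-to-peak amplitude maps, scar / border /
  healthy voltage classification (bipolar 0.5 / 1.5 mV, unipolar
  3 / 5 mV), amplitude-zone histograms, and notch-based fragmentation
  counts.
* **A synthetic generator**: icosphere meshes, an edge-graph wavefront
  at physiological conduction speed, calibrated biphasic templates, a
  low-amplitude fragmented scar patch, and the three noise components —
  with complete ground truth, standing in for patient recordings that
  are not redistributable.

## Worked example

```r
library(ecgidsp)

cfg  <- reduced_infarct_config(seed = 1)   # 252 nodes, 3 s at 2048 Hz, wide inferior scar
scen <- generate_scenario(cfg)
res  <- run_pipeline(list(scenario = cfg, seed = 1), "artifacts/")

length(res$beats)                          # 3   (one window per simulated beat)
table(res$tissue$label)
#>    scar  border healthy
#>      99      16     137
dice_coefficient(res$tissue$label == "scar", scen$truth$scar_nodes)
#> 0.8622222
amplitude_histogram(res$vpp, c(1.5, 4))
#> [-Inf,1.5)  [1.5,4.0)  [4.0,Inf)
#>        115          8        129
delay_seconds(40, 2048)                    # 0.01953125 s
delay_distance(0.3, delay_seconds(40, 2048))
#> 0.005859375 m
```

Reading the numbers: the θ<sub>Vα</sub> bipolar amplitude map classifies
99 nodes as scar (< 0.5 mV peak-to-peak); against the 126 ground-truth
scar nodes this is a Dice overlap of 0.86 — scar nodes on the patch rim
have a healthy maximum-amplitude neighbor and are intrinsically
classified healthy, which bounds the achievable overlap. The histogram
splits the mesh into the three amplitude zones seen in bipolar voltage
maps (low / intermediate / high). The last two numbers are the delay
arithmetic behind the 40-sample default: 0.0195 s of delay corresponds
to ~6 mm of wavefront travel, a conventional catheter's electrode
interspace.

A command-line front end wrapping the same functions ships in
`inst/cli/ecgidsp.R` (subcommands `simulate`, `preprocess`, `mmode`,
`autocorr`, `bipolar`, `maps`, `run`).

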