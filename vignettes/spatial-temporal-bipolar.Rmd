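---
title: "Spatial-temporal conditioning and bipolar electrogram construction for meshed unipolar potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-temporal conditioning and bipolar electrogram construction for meshed unipolar potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgidsp)
```

## The problem

Electrocardiographic imaging (ECGI) reconstructs epicardial potentials at
hundreds of mesh nodes simultaneously. Each reconstructed trace behaves
like a *unipolar* electrogram: it mixes local activation with far-field
activity from the rest of the heart. Clinical electrophysiology, however,
reasons largely in terms of *bipolar* electrograms — differences between
two closely spaced electrodes — whose amplitude and morphology underpin
voltage mapping (scar / border / healthy classification) and fragmentation
assessment. `ecgidsp` implements the processing chain needed to move from
a meshed unipolar potential field to clinically interpretable bipolar
signals and maps, together with diagnostics that expose how conventional
one-signal-at-a-time ("atomic") preprocessing interacts with the strong
spatial correlation of these fields.

The package operates on two containers: a `tri_mesh` (vertices in mm,
triangles) whose edge set defines each node's one-ring neighborhood
$\eta_i$, and a `potential_field` (nodes × samples, mV, with sampling
frequency $f_s$). The measurement model is additive,

$$v_m(s_i, t) = v(s_i, t) + N(s_i, t) + B(s_i, t) + R(s_i, t),$$

with white Gaussian noise $N$, baseline wander $B$ and other interference
$R$; preprocessing estimates and removes $B$ and high-frequency noise,
and every decomposition in the package is conservative (the removed
component is returned alongside the cleaned one, and they sum back to the
input sample-exactly).

## Preprocessing

**Baseline wander** is estimated per node by a natural cubic spline with
knots every `Tw` seconds (first and last knots clamped to the record
ends). The knot ordinate rule is configurable:

* `"sample"` (default): interpolate the signal value at the knot instant.
  This is the classic cubic-spline detrending construction and the one
  that makes knot-separation misadaptation *observable*: when `Tw` is
  short relative to the beat period, knots land on depolarization
  deflections and the baseline estimate acquires beat-periodic content.
* `"mean"` / `"median"`: windowed statistics over `Tw`-wide windows.
  These are more robust to deflections — the median almost completely so,
  which also means a median-knot baseline can *never* exhibit the
  short-`Tw` misadaptation signature. We therefore ship `"sample"` as the
  default and keep the robust rules as options.

**High-frequency noise** is removed with a zero-phase Butterworth low-pass
filter: a 9th-order design at 100 Hz cutoff (both configurable), applied
forward and backward so the net phase is zero and the effective magnitude
response is the squared one-pass response. Because a causal 9th-order
filter cannot have zero phase, "9th-order zero-phase" is implemented as
the forward-backward cascade. `signal::filtfilt` alone leaves start-up
transients when a record begins away from zero, so the filter is applied
to an odd-reflection extension of each trace and the padding is trimmed
afterwards; a constant record then passes through unchanged to numerical
precision.

**Beat segmentation** is deliberately minimal: the across-node RMS
envelope is smoothed (50 ms moving average), thresholded at 30% of its
maximum, and each supra-threshold region is expanded by 50 ms margins and
clipped to the record. All three constants are arguments. This is not a
QRS delineator; it only isolates analysis windows for the bipolar stage.

## M-mode analysis and misadaptation diagnostics

An M-mode is the time–space stack of signals along an ordered line of
mesh nodes. Because the original line selections on patient geometry were
manual, `select_path()` substitutes the shortest edge-path (Dijkstra over
the triangle edge graph with Euclidean edge lengths) between two chosen
nodes, which is reproducible and deterministic. Geodesic (surface-exact)
paths are out of scope.

The spatial-temporal autocorrelation of an $S \times T$ M-mode field is
the full linear (zero-padded) 2-D autocorrelation
$R_x(\lambda, \tau) = \sum_{s,t} x(s,t)\,x(s+\lambda, t+\tau)$, optionally
normalized so $R_x(0,0) = 1$. Small fields ($S\,T \le 4096$) are computed
by direct summation — exact for integer inputs, which is what the
brute-force oracle tests rely on — and larger fields via FFT, identical up
to float round-off. Spatial lags are reported in path-index units because
M-mode node spacing is not uniform; the mean inter-node spacing in mm is
carried as metadata.

Marginal slices ($\lambda = 0$ and $\tau = 0$) summarise the purely
temporal and purely spatial structure. `misadaptation_stats()` reduces
the temporal marginal of a baseline residual to two numbers: the count of
prominence-significant positive-lag peaks (periodicity ⇒ the spline
tracked beat content ⇒ `Tw` too short) and the mean absolute
autocorrelation beyond 1.5 s (heavy tails ⇒ slow trends left behind ⇒
`Tw` too long). On synthetic ~1 s-period beats the orderings
peaks(0.5 s) > peaks(1 s) and tail(2 s) > tail(1 s) reproduce; the tail
ordering is qualitative and its margin varies with the wander
realization.

Polarity alignment (`align_polarity()`) multiplies rows whose Pearson
correlation with a reference row is negative by −1; zero or undefined
correlations are left untouched and the reference defaults to the first
row of the stack.

## DSPOs and bipolar electrograms

For node $i$ with neighborhood $\eta_i$, a DSPO chooses the reference
trace subtracted from the exploratory trace over the analysis window
$t_w$:

| operator | reference |
|---|---|
| `theta_V` / `theta_v` | neighbor with max / min peak $|v|$ over $t_w$ |
| `theta_D` / `theta_d` | neighbor at max / min Euclidean distance |
| `theta_m` | virtual reference: sample-wise mean of neighbor traces |
| `theta_r` | seeded uniform random neighbor |
| `theta_V_alpha` | max-$|v|$ applied to traces shifted $\alpha$ samples earlier |
| `ftd` | the node's own trace shifted by $\alpha \ge 1$ samples |

The bipolar electrogram is $\beta(s_i, t_w) = v(s_i, t_w) - v(s_k, t_w -
\alpha)$ with sign convention exploratory minus reference; $\alpha = 0$
for the plain operators. Design choices worth knowing:

* The amplitude metric is the **peak absolute value** of the trace over
  the window (not peak-to-peak, not RMS) — the literal reading of the
  operator definitions.
* `theta_m` is implemented as a **mean trace** used as a virtual
  reference electrode. A mean of absolute amplitudes is a scalar and
  cannot be subtracted as a time signal; this is the only reading that
  yields a bipolar waveform.
* Ties (e.g. identical neighbor amplitudes) break toward the **lowest
  node index**, deterministically.
* **No zero padding**: if the shifted window leaves the record the
  operation errors, rather than fabricating discontinuities.
* The default delay for `theta_V_alpha` is **40 samples**; at 2048 Hz
  that is `delay_seconds(40, 2048)` ≈ 0.0195 s, during which a wavefront
  at 0.3 m/s travels `delay_distance(0.3, 0.0195)` ≈ 6 mm — the
  electrode interspace of a conventional catheter, which is why this
  delay restores familiar bipolar morphology.

On a 252-node sphere mesh with ~6–8 mm edges, a delayed reference can
nearly cancel the exploratory deflection when a neighbor sits almost
exactly one delay-length upstream of the wavefront; this is intrinsic to
the operator at coarse mesh spacing, not an implementation artifact.

## Clinical indices

Peak-to-peak amplitude maps feed the standard voltage classification:
bipolar scar < 0.5 mV, border 0.5–1.5 mV, healthy ≥ 1.5 mV; unipolar
scar < 3 mV, border 3–5 mV, healthy ≥ 5 mV. Boundary convention (the
clinical thresholds are quoted with loose inequalities): scar strictly
below the low edge, healthy at or above the high edge; both edges are
arguments. Amplitude-zone histograms use half-open bins with an open top
bin, so counts always conserve the node total.

Fragmentation was assessed manually in the source studies;
`count_notches()` is an explicit algorithmic stand-in: restrict to the
main deflection ± 50 ms, find local extrema whose adjacent swings are at
least 0.05 mV, discount the two extrema of a clean biphasic deflection,
and count each remaining reversal pair as one notch. Both constants are
arguments, and the count is monotone in the prominence threshold.

## The synthetic scenario generator

No patient recordings ship with the package; `generate_scenario()`
produces a fully ground-truthed stand-in:

* **Mesh**: an icosphere (subdivided icosahedron, $10f^2 + 2$ vertices),
  radius 30 mm. Subdivision 9 gives 812 nodes — the scale of a clinical
  epicardial reconstruction (802 nodes at 2048 Hz, ~10 s) — and the
  reduced scenario (`reduced_infarct_config()`) uses subdivision 5
  (252 nodes, 3 s, 3 beats), the size at which the whole validation
  pipeline runs in seconds on one CPU.
* **Wavefront**: activation time = shortest edge-path distance from the
  origin divided by the conduction speed (default 0.4 m/s, physiological
  range 0.3–0.5). An edge-graph wavefront is exactly testable, unlike an
  eikonal solver, and adequate at this scale.
* **Waveforms**: an RS-like biphasic deflection (derivative-of-Gaussian,
  σ = 8 ms, R/S asymmetry 1.5) rescaled so the peak-to-peak amplitude is
  exact: 8 mV for healthy nodes; scar nodes are scaled by 0.03
  (0.24 mV, below the 0.7 mV reported over dense scar) and superpose
  two sharp jittered sub-deflections to emulate fragmentation.
* **Scar patch**: a geodesic cap of radius 47 mm about the node nearest
  the −z pole — a wide, roughly hemispheric inferior scar. The width is
  deliberate: under any max-amplitude DSPO, scar nodes on the patch rim
  have a healthy max-$|v|$ neighbor and are therefore classified healthy,
  so the achievable Dice overlap is bounded by roughly
  $2I/(S+I)$ where $S$ is the scar count and $I$ the rim-free interior.
  At 252 nodes a narrow patch is mostly rim; the wide cap keeps the
  ceiling near 0.87.
* **Noise**: Gaussian sd 0.02 mV; baseline wander 0.3 mV as a per-node
  random-phase sum of five sinusoids in 0.05–0.4 Hz (within the
  physiological wander band, capped at 0.4 Hz so 1 s spline knots can
  represent it); powerline interference defaults to 0 mV because 50 Hz
  sits inside the 100 Hz passband and mains notch filtering is out of
  scope. Beats are placed at 0.3 s + k·1 s so deflections never coincide
  with integer-second spline knots.

What passing tests on this generator do **not** show: the templates are
not fitted to real electrogram morphology (no quantitative widths were
available), there is no repolarization wave, no fiber anisotropy, no
torso forward model, and noise components are stationary. Results on the
synthetic scenario validate the operators and the pipeline plumbing, not
clinical performance.

## Worked example

```{r example, eval = FALSE}
cfg <- reduced_infarct_config(seed = 1)
scen <- generate_scenario(cfg)
res <- run_pipeline(list(scenario = cfg, seed = 1), tempdir())

# scar recovery from the delayed max-amplitude bipolar map
dice_coefficient(res$tissue$label == "scar", scen$truth$scar_nodes)
#> about 0.85-0.87 depending on the noise seed

# conduction speed from ground-truth isochrones
d <- simulate_wavefront(scen$mesh, cfg$origin, cfg$speed) * cfg$speed * 1000
fit <- lm(scen$truth$activation[, 1] - cfg$beat_times[1] ~ d)
1 / (coef(fit)[["d"]] * 1000)
#> 0.4 (exact, by construction)
```

## Numerical choices and limitations

* Angles in `neighbor_geometry()` live in the tangent plane defined by
  the area-weighted average of incident triangle normals, measured from
  the projection of the lowest-index neighbor — deterministic and
  mesh-intrinsic, since the data impose no preferred direction.
* Node indices are 1-based throughout the R API; mesh files (OFF, PLY,
  JSON) keep the 0-based convention of those formats and the readers and
  writers convert.
* Degenerate inputs fail loudly: coincident neighbor vertices,
  disconnected path endpoints, windows (or delayed windows) leaving the
  record, flat reference rows in polarity alignment, and mis-specified
  cutoffs all raise errors naming the offending node or line.
* Isolated vertices (no incident triangle) get empty neighborhoods and
  are excluded from DSPO processing with `NA` map entries.
* `theta_r` draws through a temporary seeded RNG state, so it is
  reproducible and leaves the caller's RNG untouched.
* The exact rules by which the original recordings were beat-synchronized
  and low-quality torso channels discarded were not available, so no
  channel-rejection stage is attempted here.
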