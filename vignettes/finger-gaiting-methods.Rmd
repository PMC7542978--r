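---
title: "Decomposing in-hand manipulation: methods and design notes"
author: "gaitglove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing in-hand manipulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitglove)
```

## The problem

When a person turns a small object over in one hand at a steady pace,
the thumb guides the object while opposed fingers stabilize it; fingers
that reach their joint limits are released and replaced by free fingers,
a strategy called *finger gaiting*. A 29-sensor data glove records this
as a multichannel time series: bend sensors at the finger MCP and PIP
joints and the thumb MCP/IP joints, four abduction sensors, a palm-arch
and a thumb-cross (CMC opposition) sensor, fingertip pressures, and two
orientation quaternions. Each acquisition ("run") spans 20 s at 50 Hz;
analysis uses the final 800 frames (16 s), after the subject has locked
onto the instructed 1-Hz pace. Nineteen channels carry the prehensile
signal (the quaternions and two pressure sensors do not) and enter the
analysis; twelve of them (ten bends, palm arch, thumb cross) define the
joint network.

`gaitglove` implements the full analysis chain — per-run PCA, sign
alignment, a cluster taxonomy of spatial patterns, temporal (frequency
and delay) statistics, signed correlation networks, and 3D fingertip
trajectories — plus a synthetic generator whose ground truth makes the
chain testable end to end.

## Per-run decomposition

For one run, let $X \in \mathbb{R}^{800\times 19}$ hold the calibrated
amplitudes. The *residual matrix* is the column-centered
$R = X - \mathbf{1}\bar{x}^\top$; no variance scaling is applied, so
expression coefficients stay in calibrated amplitude units (all
channels already share the 0–1000 scale). The SVD
$R = U\,\mathrm{diag}(d)\,V^\top$ yields, per component $k$: the sensor
expression pattern (EC) $v_k$, the time course $u_k$, and the
eigenvalue $d_k^2/(n-1)$; the variance fraction is
$d_k^2 / \sum_j d_j^2$. ECs and time courses are orthonormal by
construction.

Salience uses the Guttman–Kaiser rule generalized to a covariance PCA:
the number of eigenvalues strictly exceeding the run's mean eigenvalue.
(The classical "eigenvalue > 1" form presumes correlation-scaled input;
the mean-eigenvalue form is its scale-free equivalent and reproduces
non-integer cohort means when averaged over runs.)

A zero-variance channel is retained with a warning rather than dropped:
dropping would silently change the channel indexing that every
downstream stage relies on.

## Sign alignment

PCA determines each component only up to sign, so pooling ECs across
runs requires alignment. It proceeds in two stages, per component
index:

1. **Within subject.** For one subject's runs, find per-run signs
   maximizing the summed pairwise Pearson correlation of the signed
   ECs. With $n$ runs the $2^{n-1}$ sign patterns are enumerated
   exactly for $n \le 12$ (six runs in the study protocol); beyond
   that a deterministic greedy pass (anchor to the first run, then
   sweep single-sign flips to a fixed point) is used. Ties keep $+1$,
   so mutually uncorrelated ECs are left untouched.
2. **Across subjects.** The same objective over one sign per subject,
   applied to the subject-mean ECs of stage 1 (22 subjects exceeds the
   exact-enumeration cutoff, so the greedy pass applies). Finally a
   single global sign is chosen so the summed loading over the thumb
   cross and finger MCP/PIP channels is positive — "positive" then
   reads as increased bending of those sensors.

Signs are applied jointly to the EC and its time course, which leaves
eigenvalues and the reconstruction invariant (a fact the test suite
asserts).

## Cluster taxonomy and sensor salience

All $3N$ aligned ECs (3 components × $N$ runs) are clustered by
k-means with $k=3$ under correlation distance $1 - r$: items and
centroids are row-centered and unit-normalized, so the distance
compares pattern *shape*, not scale. k-means is
initialization-dependent and the upstream description is silent on
restarts, so the seed and the number of restarts (default 50, best
total distance wins) are explicit parameters. A replicate that empties
a cluster is re-initialized.

Clusters are labeled with component ranks by maximum-agreement
*bijective* matching (all $3!$ permutations scored), not per-cluster
plurality: pluralities can collide, and the downstream bookkeeping
(correct flags, misassignment tables) requires a bijection. An item is
"correct" when its component rank equals its cluster's label.

Sensor salience within a cluster uses the correctly assigned items
only: an omnibus Kruskal–Wallis test across the 19 per-sensor EC
distributions, then Dunn-type pairwise rank comparisons (pooled-rank
$z$ statistics with tie correction) under Bonferroni control. The
Bonferroni factor defaults to the number of pairs,
$\binom{19}{2} = 171$ — the behaviour of the standard post-hoc
multiple-comparison routines. A literal factor of 19 would not control
the familywise error over 171 dependent pairwise tests (expected false
positives $171 \times 0.05/19 \approx 0.45$ under the null); the
factor is an argument, so the smaller correction can be requested
explicitly. The acceptance suite verifies both calibration properties:
per-pair uncorrected false-positive rate near 0.05 and familywise rate
at or below 0.05.

## Temporal statistics

**Spectra.** Magnitude DFT of the mean-removed 800-frame time course,
no taper, 0.0625 Hz resolution, unit-maximum normalized; cohort mean
spectra average the normalized spectra. One caveat is documented
rather than patched: when the realized frequency falls between bins,
scalloping can let a strong harmonic overtake the fundamental in a
*single run's* argmax. Cohort means are unaffected (fundamental lobes
align across runs, harmonic lobes disperse), and the peak-interval
estimator below is the per-run frequency tool.

**Delays.** The delay between two component time courses is the
integer lag within ±25 frames (half a 1-Hz cycle at 50 Hz) maximizing
the normalized cross-correlation magnitude, positive when the second
series lags the first; ties break toward the smaller absolute lag, so
the estimate is antisymmetric whenever the optimum is unique. A true
offset beyond the cap aliases by one task period (a 30-frame shift of
a 1-Hz train reports −20); parameter-recovery checks therefore compare
modulo the realized period. The *gaiting fraction* is the share of
runs whose absolute delay falls inside a window (50 frames = 1 s; the
100-frame window with a 50-frame cap serves as the 2-s diagnostic).

**Sensor-level frequencies.** Each channel is low-pass filtered
(linear-phase windowed-sinc FIR, Hamming window, order 50, 10 Hz
cutoff, applied centered with reflective padding so peaks do not
move), normalized to unit maximum, and the frequency taken as the
reciprocal mean inter-maximum interval. Peak detection keeps maxima at
least 0.4 s apart with topographic prominence at least 30% of the
filtered range. The separation follows the task band; the prominence
default was raised from an initial 10% because pulse-like 1-Hz signals
carry secondary lobes near 20% of range that would otherwise be
counted as cycles at sub-1-Hz rates. A minima-based estimate confirms
the maxima-based one (warning above 10% deviation); zero crossings
serve only as a fallback when minima are undetectable, since
multi-harmonic pulses cross zero several times per cycle. Group
statistics compare the thumb group (thumb MCP/IP, thumb cross, palm
arch), finger-MCP and finger-PIP groups: per-run group means, two-sided
rank-sum tests between hands, and a Friedman test across groups within
hand (runs as blocks).

## The joint network

Per run, the 12×12 Pearson matrix of the network channels (diagonal
zeroed) is computed; runs whose dominant component was correctly
assigned are averaged elementwise into a signed weighted network —
negative weights are kept. Metric conventions, stated explicitly
because the upstream naming is loose:

* **Connectivity and paths** use weight magnitudes with edge length
  $1/|w|$; global efficiency is the mean inverse shortest-path length
  over pairs (disconnected pairs contribute 0). Negative correlations
  carry signal for connectivity, which is how a dense signed network
  can sit near efficiency 1.
* **Small-world index** $\sigma = (C/C_{\mathrm{null}})/(L/L_{\mathrm{null}})$
  with the Onnela weighted clustering coefficient $C$ and
  characteristic path length $L$; null references are ensemble means.
* **Small-world propensity** $\varphi = 1-\sqrt{(\Delta_C^2+\Delta_L^2)/2}$
  with $\Delta_C, \Delta_L$ the clamped deviations of $C$ and $L$ from
  lattice and random references built from the same weight multiset
  (strongest weights to the shortest ring distances). Both $\sigma$
  and $\varphi$ are convention-dependent; outputs should be compared
  only within one convention.
* **Null model**: 100 graphs, each the observed weight multiset
  reassigned via 1000 random pairwise swaps, seeded; observed metrics
  are compared to the ensemble by a two-sided rank-sum test.
* **Modules**: Louvain local moving on signed modularity with the
  asymmetric treatment of negative weights
  ($Q = Q^+/v^+ - Q^-/(v^+ + v^-)$), resolution $\gamma = 1$,
  consensus over 100 seeded restarts (most frequent partition; ties go
  to the higher modularity). Thresholding (0.05 steps) is a display
  and subnetwork diagnostic; metrics are computed unthresholded.

## 3D trajectories

A trajectory is the fingertip path between consecutive maximal thumb
extensions. The extension scalar is not defined upstream; the default
operationalization is the thumb tip's distance from the time-mean
centroid of the 23-point hand model, with a single-axis coordinate as
the configurable alternative. Each trajectory is resampled to 100
points *uniformly in cumulative arc length* — a deliberate deviation
from naive frame-uniform resampling, so speed variation along the path
does not distort the mean shape; endpoints are preserved and the
resampled path length changes by under 2% for smooth loops. The mean
trajectory is the pointwise mean; per point, the 3×3 covariance across
trajectories scaled by $\sqrt{\chi^2_{3,0.95}}$ gives the 95% error
ellipsoid. Rank-deficient covariances (identical trajectories) are
flagged, not fatal. Units: mm internally, cm/s for speeds.

## The synthetic stated world

The generator emits what the analysis assumes: $K=3$ latent grasp
configurations sharing one per-run task frequency, phase-shifted
within the cycle, expressed over the 19 channels through fixed loading
patterns, plus noise.

* **Waveform.** A harmonic pulse
  $s(t)=\sum_{m=1}^{3} w_m \cos(2\pi m f t)$ with weights
  $(1,\,0.6,\,\sqrt{0.68})$. Two properties motivated this over a
  raised-cosine power train: (a) whenever
  $w_3^2 = (w_1^2+w_2^2)/2$, copies shifted by a third of a period are
  *exactly* orthogonal over full cycles, so with the default delays
  $(0, 1/3, 2/3)$ s the latent time courses are orthogonal and PCA
  recovery is exact at zero noise — a property the recovery tests
  require and that no single-frequency shift family of an
  $a_1$-dominant pulse can deliver; (b) the fundamental still
  dominates both the waveform (one major maximum per cycle) and the
  spectrum. The weights are configurable.
* **Defaults** (chosen once, from the task protocol where stated,
  otherwise from what a motor-control lab would call realistic):
  1.0 Hz base frequency (the instructed pace) with 0.02 Hz per-run
  jitter; amplitudes $(1, 0.6, 0.35)$ — the upstream account gives no
  quantitative ratios, only a dominance ordering, and PC1 typically
  carrying about half the salient variance motivates the 1 : 0.6
  step; additive white noise SD 0.03 in latent units, about 10% of
  the weakest component's amplitude (the level at which the recovery
  properties are specified); per-run loading jitter SD 0.03; cohort
  22 subjects × 6 runs, mirroring the study protocol. Output is
  affinely mapped into the calibrated 0–1000 range (offset 500, gain
  from the run's maximum excursion), which leaves PCA structure
  untouched.
* **Loadings.** `default_loadings()` encodes the qualitative spatial
  opposition (thumb cross/palm arch vs finger PIPs; finger MCP/PIP vs
  thumb bends; a weak mixed third pattern) and is then
  orthonormalized. Orthogonality is required for clean recovery but
  caps how anti-thumb component 2 can be — a vector orthogonal to
  component 1 cannot be strongly negative on all of component 1's
  positive channels — so component 2's thumb-cross/palm-arch entries
  land near zero. `module_loadings()` uses disjoint groups
  (thumb+palm, MCP, PIP) and is the planted truth for module-recovery
  checks.
* **Trajectories.** Five fingertips trace circular loops (radius per
  tip) over a static 23-point hand, with the thumb loop oriented so
  its distance from the hand centroid peaks exactly once per cycle.

**What the generator does not emulate** — and hence what a green test
does not establish: real sensor nonlinearity and calibration drift,
pressure-channel dynamics, non-stationary pacing within a run,
inter-subject differences in loading *structure* (only magnitude
jitter is modelled), non-orthogonal real ECs, and hand asymmetries.
Cohort-level numbers from the deposited study data (cluster counts per
hand, 1.03 Hz spectral peaks, efficiency ≈ 0.95) are reproducible only
against that data and are deliberately not asserted by the test suite.

## Other design notes

* Config files are JSON (round-tripped losslessly by `jsonlite`); no
  YAML parser is assumed on the target system.
* The pipeline recomputes every stage on each call instead of caching
  stage artifacts by content hash: a full synthetic cohort runs in
  seconds, so cache complexity buys nothing. Determinism is the
  contract: same config and seeds, byte-identical report.
* Warnings raised inside pipeline stages are collected into the
  report (`report$warnings`) rather than dropped.
* Stage seeds (k-means, null ensemble, Louvain) are derived from the
  master seed but stored explicitly in the config, so every stochastic
  stage is independently reproducible.

## Known limitations

* Binary C3D motion files are not parsed; 3D point data enter via the
  documented TSV export.
* $\varphi$ and $\sigma$ follow the conventions above; other toolboxes
  implement different lattice/null constructions and will return
  different absolute values on the same graph.
* The Louvain implementation uses local moving with restart consensus
  (no aggregation phase); for 12-node networks with the planted
  structures of interest this is exhaustive in practice, but very
  large graphs are out of scope.
* The raw vendor export layout is unknown upstream; the TSV dialect
  here is a repository convention, and a thin adapter may be needed
  for external data.
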