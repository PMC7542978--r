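# gaitglove

Analysis of repeated in-hand object manipulation recorded with a
29-sensor data glove, built around the *finger gaiting* question: can a
1-s manipulation cycle be decomposed into a small set of grasp
configurations — thumb opposition against changing finger support —
that recur at the task frequency with sub-second delays between them?

The package is aimed at motor-control and rehabilitation researchers
working with multichannel kinematic time series (data gloves, motion
capture): it provides the full analysis chain as tested, reusable
functions, and a synthetic generator with known ground truth so the
chain can be validated without access to any particular dataset.

## What it computes

For each 800-frame run $X \in \mathbb{R}^{800\times19}$ (16 s at
50 Hz, 19 prehensile channels):

* **Decomposition** — PCA of the column-centered matrix via SVD,
  $R = U\,\mathrm{diag}(d)\,V^\top$: per component an expression
  pattern (EC) over sensors, a time course, and a variance fraction
  $d_k^2/\sum d_j^2$; Guttman–Kaiser salience (eigenvalues above the
  run mean).
* **Sign alignment** — two-stage (within subject, then across
  subjects) maximization of summed pairwise EC correlations, plus a
  canonical global sign (positive = increased bending of thumb
  cross / finger MCP / PIP).
* **Pattern taxonomy** — k-means (k = 3) under correlation distance
  $1-r$ with bijective cluster-to-component labeling; Kruskal–Wallis +
  Bonferroni post-hoc sensor salience.
* **Temporal statistics** — normalized spectra; signed delays between
  component time courses, capped at ±25 frames, and the fraction of
  runs with $|\mathrm{delay}| < 1$ s (the finger-gaiting statistic);
  FIR-filtered peak-interval frequencies per sensor group with
  rank-sum / Friedman tests.
* **Joint network** — mean signed 12×12 correlation network; global
  efficiency $E = \mathrm{mean}_{i<j}\, 1/d_{ij}$ with edge length
  $1/|w|$; small-world index σ and propensity φ against a
  weight-multiset null ensemble; signed Louvain modules (γ = 1).
* **3D trajectories** — fingertip paths segmented at thumb-extension
  maxima; speeds (path length / duration), arc-length-uniform
  resampling to 100 points, mean trajectory with 95% error ellipsoids.

See `vignettes/finger-gaiting-methods.Rmd` for the model, conventions
and design decisions.

## Worked example

Simulate a 4-subject cohort with the generator's default stated world
(three grasp-configuration components at 1 Hz, delays of a third of a
cycle, decreasing amplitudes) and run the full pipeline:

```r
library(gaitglove)
cfg <- pipeline_config(synthetic = synthetic_spec(n_subjects = 4, seed = 1),
                       seed = 1)
report <- run_pipeline(cfg)
print(report)
#> <cohort_report> right hand: 24 runs / 4 subjects
#>   GK salient components: 3.00 +/- 0.00; top-3 variance 99.1%
#>   correct cluster assignments: 24 / 24 / 24
#>   within-window delay fractions: PC1_PC2=1.00, PC1_PC3=1.00
#>   network: e_glob 0.659, phi 0.00, sigma 0.89, 3 modules
```

Reading the output: every run shows exactly 3 salient components
(Guttman–Kaiser) carrying 99% of the variance — the three planted
grasp configurations; all 72 component patterns are assigned to their
matching cluster; every PC1–PC2 delay falls inside the 1-s window
(fraction 1.00), the finger-gaiting signature; and the Louvain
partition of the joint network returns 3 modules. The per-group
frequencies sit at the instructed pace:

```r
print(report$group_frequencies)
#> <group_frequency_table>
#>  group  hand  n     mean         sd
#>  Thumb right 24 1.013937 0.01601010
#>    MCP right 24 1.000538 0.01808044
#>    PIP right 24 1.004103 0.02201545
```

With `loadings = module_loadings()` the network modules recover the
planted thumb / MCP / PIP groups exactly (adjusted Rand index 1); see
`validate_synthetic()` for the whole parameter-recovery ledger.

Real runs are read from self-describing TSV files (`read_run()`,
`#key=value` metadata lines, one row per frame), trimmed with
`trim_run(run, 800)` and restricted with
`select_channels(run, default_layout()$relevant19)`. A command-line
front end is installed at `inst/cli/gaitglove.R`
(`simulate | run-all | validate`).

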