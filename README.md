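# combfork

Replication-fork analysis for dual-pulse DNA molecular combing assays, with a
stochastic fiber simulator and a synthetic image renderer so that the whole
analysis is exercisable without experimental data.

## The problem

In a DNA combing experiment, cells are labeled with two sequential
thymidine-analog pulses (here 25 µM IdU for 30 min, then 200 µM CldU for
30 min), their DNA is stretched uniformly on silanized coverslips, and each
replication fork leaves a two-color track whose lengths (in kb, via the
combing constant) report fork speed and origin behavior. Two readouts matter
for replication-stress studies:

- **Fork speed.** When the second-label (CldU) track is flanked by DNA
  counterstain, `v = (L_IdU + L_CldU) / (t1 + t2)`. When the CldU track runs
  off the fiber end its length is censored and `v = L_IdU / t1` (first label
  only).
- **Origin symmetry.** Each origin fires two divergent forks. With
  `d = |vL − vR| / max(vL, vR) × 100`, a unit is *symmetric* (`d < 30`),
  *asymmetric* (`30 ≤ d < 100`), or *unidirectional* (`d = 100`, i.e. only
  one fork ever departed). Elevated unidirectional and asymmetric fractions
  are the combing signature of replicative stress, e.g. after depletion of
  the cohesin subunit RAD21.

`combfork` implements the full chain: ground-truth simulation of combed
fibers (Poisson origins, uniform firing times that may precede labeling,
truncated-normal fork speeds, dead-before-labeling forks, exponential
permanent stalling), exact dual-pulse labeling geometry, rendering into
multi-page 16-bit TIFF strips with PSF blur and Gaussian noise, 1-D track
detection (Otsu thresholding, gap merging, length filtering), fork calling
and replication-unit pairing, symmetry classification, and two-condition
statistics (pooled two-tailed Student t, Cohen's d, class-proportion
chi-square).

## Worked example

Simulate a control and a cohesin-depleted condition (the depleted condition
has ten times the dead-fork probability and slightly faster forks), run the
segment-level pipeline, and compare:

```r
library(combfork)

config <- list(
  seed = 1, skip_imaging = TRUE,
  conditions = list(
    control = list(simulate = list(
      n_fibers = 490, fiber_length_kb = 700, origin_rate_per_kb = 1/700,
      firing_time_window_min = c(-20, -5), origin_edge_margin_kb = 200,
      p_dead = 0.03, stall_rate_per_min = 0.002,
      speed_kb_min = list(dist = "normal", mean = 1.4, sd = 0.2))),
    depleted = list(simulate = list(
      n_fibers = 680, fiber_length_kb = 700, origin_rate_per_kb = 1/700,
      firing_time_window_min = c(-20, -5), origin_edge_margin_kb = 200,
      p_dead = 0.30, stall_rate_per_min = 0.002,
      speed_kb_min = list(dist = "normal", mean = 1.55, sd = 0.2)))))

res <- run_pipeline(config, "out")
print(res$summaries$control)
print(res$summaries$depleted)
print(res$comparison)
```

```
Condition 'control': 348 units (345 classifiable, 3 censored), 676 forks
  classes: symmetric 77.1%, asymmetric 18.0%, unidirectional 4.9%
  fork speed: mean 1.333 kb/min, sd 0.289 (n = 673)
Condition 'depleted': 401 units (388 classifiable, 13 censored), 623 forks
  classes: symmetric 49.7%, asymmetric 7.2%, unidirectional 43.0%
  fork speed: mean 1.516 kb/min, sd 0.253 (n = 609)
Comparison: depleted vs control
  speed: t = 12.011 (df 1280.0), two-tailed p = 1.44e-31, Cohen's d = 0.672
  classes: chi2 = 144.713 (df 2), p = 3.77e-32
```

The depleted condition shows the expected dramatic rise of unidirectional
units (4.9% → 43.0%), a highly significant class-proportion shift, and a
moderate positive speed effect (d ≈ 0.7). `run_pipeline()` also writes
ground-truth, segment, fork and unit TSV tables, a `results.json`, and a run
log carrying the seed and config digest needed to reproduce the run; with
`skip_imaging = FALSE` it additionally renders and re-detects every fiber
through the imaging arm (TIFF output). The same stages are available as a
thin command-line tool in `inst/cli/combfork`
(`simulate | render | detect | measure | compare | run`).

## Acceptance script

`scripts/acceptance.R` re-runs the end-to-end two-condition analysis from
scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It prints both condition summaries and the comparison, and writes the JSON
report to `--out`.
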