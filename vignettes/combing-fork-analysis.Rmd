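---
title: "Measuring replication fork speed and symmetry from dual-pulse combing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring replication fork speed and symmetry from dual-pulse combing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combfork)
```

## The measurement model

DNA combing stretches genomic fibers uniformly on glass, so lengths measured
on an image convert to kilobases through a fixed combing constant (2 kb/µm by
community convention; at 0.1 µm pixels this gives 0.2 kb per pixel, the
package default). Cells are labeled with two sequential nucleotide-analog
pulses — IdU for `t1` = 30 min, then CldU for `t2` = 30 min — so a fork
active through both pulses leaves a two-color track, read outward from its
origin: IdU proximal, CldU distal.

All package coordinates are half-open, 0-based kb intervals; time zero is
the start of pulse 1. A fork fired at time `t_fire` at origin position `x0`
with speed `v` sits at `x0 ± v · (min(t, t_stall) − t_fire)` for
`t ≥ t_fire`: the interval swept during `[0, t1)` is its IdU track, during
`[t1, t1 + t2)` its CldU track, and anything replicated before `t = 0` is
unlabeled. `apply_labeling()` evaluates this geometry exactly, clipping to
the fiber.

Fork speed follows the assay's two rules, implemented in `fork_speed()`:

- flanked CldU (distal end abuts counterstain): `v = (L_IdU + L_CldU) / (t1 + t2)`;
- unflanked CldU (run-off at a fiber end, length censored): `v = L_IdU / t1`.

The denominator is always the summed duration of the pulses whose labels
enter the numerator — the only reading under which both formulas are
dimensionally consistent.

Each origin launches two divergent forks; symmetry is scored per origin
(`classify_symmetry()`) via the percent difference
`d = |vL − vR| / max(vL, vR) × 100`, with `d < 30` symmetric,
`30 ≤ d < 100` asymmetric, and unidirectional the structural case of an
absent partner fork. Two numerical choices deserve emphasis:

- *Normalisation by the faster fork.* The class definitions fix only the
  three bands; normalising by `max(vL, vR)` is the unique choice for which a
  missing partner (speed 0) lands exactly at 100%.
- *Unidirectional is structural, not numeric.* A one-fork unit is called
  unidirectional directly; `d == 100` is never tested in floating point.
  Two present forks always classify symmetric or asymmetric, however close
  `d` comes to 100 (speeds are strictly positive).

## The fiber simulator as a stated world

`sample_fibers()` draws, per fiber: a length (fixed or lognormal), a Poisson
number of origins with intensity `origin_rate_per_kb × length`, uniform
origin positions, a uniform firing time on `firing_time_window_min`
(negative values = fired before labeling, producing the split
CldU–IdU–gap–IdU–CldU pattern; values inside pulse 1 produce a contiguous
IdU block over the origin), and independent truncated-normal fork speeds.
Two distinct failure processes map one-to-one onto the two pathological
classes:

- `p_dead`: a fork is permanently stalled *before* labeling (stall time
  −∞). It leaves no track, so its partner appears unidirectional.
- `stall_rate_per_min`: exponential hazard of permanent stalling *during*
  labeling. A mid-labeling stall shortens one side's tracks, producing
  asymmetric units (stalling is permanent; no restart is modeled).

With dead probability `q` per fork and no mid-labeling stalling, among units
with at least one labeled fork the unidirectional fraction is
`2q(1−q) / (1 − q²) = 2q/(1+q)`; the test suite verifies the pipeline
recovers this law within Monte-Carlo error.

Two placement parameters restrict the stated world deliberately. Origins on
one fiber are kept at least `2 × speed_max × (t1 + t2)` apart (redrawn by
rejection; `speed_max` is a 5-sigma bound on the speed distribution), so
labeled tracks of neighbouring units cannot collide and labeling geometry
stays closed form — fork collisions, timing programs and chromatin context
are out of scope. `origin_edge_margin_kb` (default 0) keeps origins away
from fiber ends; the population-law tests set it to one maximal track length
so no track is clipped, because the `2q/(1+q)` law and exact speed recovery
presume uncensored units. Real combing data are censored; the package
handles censoring (run-off speeds, unclassifiable calls) but the calibration
laws are only asserted where they actually hold. The paper's quantitative
fiber-inclusion criteria are unstated, so these remain free parameters
rather than guessed values.

What a green test establishes: the measurement chain is internally exact and
the classifier honors its contracts on the modeled patterns. What it does
not establish: robustness to crossing or bundled fibers, fiber curvature,
chromatic shift, antibody speckle, or restart after stalling — none of which
the generator emulates.

## Imaging and detection

`render_fiber()` draws each fiber as an axis-aligned horizontal strip
(default 24 rows) with a 5-row central band: DNA counterstain across the
whole extent, label segments as rectangular blocks (peak 1000 counts),
convolved with a Gaussian PSF (`psf_sigma_px`, default 1), plus constant
background (50) and Gaussian noise of sd `peak / snr` (default SNR 20),
then rounded to integer counts. The rounding is a camera-quantisation step
that also makes TIFF round trips bit-exact. Curvature is deliberately
excluded: it is a detection nuisance orthogonal to every downstream
computation, and straight strips keep the detector's oracles exact. Images
are stored as multi-page 16-bit baseline TIFF (one fiber per page, channels
DNA/IdU/CldU, per-page JSON metadata carrying `fiber_id` and `kb_per_px`,
plus a sidecar TSV manifest); the reader/writer pair is self-contained and
cross-checked against an independent TIFF implementation in the tests.

`detect_segments()` works in 1-D: per channel, a column-wise max projection
is thresholded, connected runs are extracted, same-channel gaps shorter than
`max_gap_kb` (default 0.5) are merged, runs shorter than `min_segment_kb`
(default 1) are dropped, and pixel runs convert back to kb (`[i0−1, i1] ×
kb_per_px` for a 1-based run `i0..i1`, so boundary error is at most one
pixel, 0.2 kb at defaults). Thresholding details matter on fibers lacking a
label:

- The Otsu level is computed from the full channel *matrix*, not the
  projection: every column contains background rows, so the matrix is
  bimodal whenever signal exists, whereas the projection of the DNA channel
  (fiber spanning the whole strip) is all-signal and would defeat a
  projection-level Otsu.
- Background level and noise are estimated from the strip's border rows,
  which are outside the fiber band by construction (a matrix-wide median is
  biased upward once the PSF halo spreads the band across most rows).
- The channel falls back to `fixed_threshold` — or to an empty result when
  none is given — when its dynamic range is below twice the background sd,
  or when the Otsu level lands inside the noise (below background + 2 sd):
  Otsu degenerates on empty channels and would otherwise split pure noise.

## Fork calling and unit pairing

`call_forks()` turns segments into forks: each IdU track spawns calls, an
adjacent CldU track (gap ≤ 1 kb by default) orients the fork toward it, and
CldU on both sides splits the IdU block at its midpoint into two diverging
forks. The midpoint split is a documented convention: the origin position
inside a contiguous block is unobservable, the midpoint is the symmetric
estimator, and equal-speed units then score exactly `d = 0`. CldU-only
tracks (origins fired during pulse 2) spawn nothing; IdU-only tracks have no
direction basis and are recorded as unclassifiable forks, excluded from
speed statistics unless rescued by pairing. `cldu_flanked` requires the CldU
distal boundary to lie at least `end_margin_kb` (default 2) inside the fiber
extent, which is taken from the DNA counterstain.

`group_units()` pairs forks left-to-right, greedily: midpoint-split halves;
then a leftward fork followed by a rightward fork diverging across an
unlabeled gap of at most `origin_gap_max_kb` (default 200, comfortably above
the widest eye a pre-labeling origin can open and below the inter-origin
separation). A directionless fork takes part in such a pair — the geometry
orients it and it gets an IdU-only speed — and two directionless tracks
across one gap become a single two-fork unit that stays unclassifiable
(orientation is genuinely unobservable without any second label). A lone
fork whose origin-proximal boundary is flanked by counterstain is a one-fork
unit — the partner never departed — and classifies unidirectional; a lone
fork at the fiber end is censored (unclassifiable), since a broken fiber
cannot be distinguished from a missing partner there. Whether the original
assay required visible counterstain beyond the silent side for
unidirectional calls is unstated; this package does, and exposes the margin.

## Comparison statistics

`compare_speeds()` uses the equal-variance two-sample Student t (two-tailed
p on `nA + nB − 2` df; a Welch option exists but is off by default, matching
the pooled effect size) and Cohen's d in the pooled-SD form
`(mA − mB)/s_pooled` — the default definition when a source names only
"Cohen's d". The per-fork (not per-fiber) unit of analysis is used
throughout, matching how combing experiments report "number of forks
analyzed". `compare_class_fractions()` is a Pearson chi-square (2 df, no
continuity correction) on the 2×3 class-count table. Degenerate inputs
(groups under 2 observations, zero pooled variance with equal means, empty
table margins) are errors, not NaNs.

The test suite's null calibration draws both groups from the generative
speed distribution directly: the flanked measurement reproduces drawn speeds
exactly for uncensored pre-pulse origins (verified separately), so under the
null the measured-speed distribution *is* the generative one, and the
calibration question — rejection rate at α = 0.05 and the magnitude of |d|
under identical conditions — reduces to sampling.

## Degenerate inputs and tie-breaks

Zero-width segments are invalid everywhere; same-channel overlap is an
error, while abutting intervals merge when a table is built with
`merge = TRUE` (the observable table of a fiber merges the two IdU arms of
an origin fired during pulse 1, as a microscope would). Matching in
`match_to_truth()` is greedy by decreasing overlap, one-to-one, and a pair
must agree on both boundaries within the tolerance. Exactly `d = 30`
classifies asymmetric ("less than 30%" is strict). A stall at exactly the
pulse boundary yields a complete IdU track and no CldU. Seeded operations
snapshot and restore the caller's RNG state, so pipeline stages do not
perturb user code; per-fiber render seeds derive from the configured seed.

## Known limitations

Inter-origin distances, fork restart, replication-timing inference and
origin-licensing models are out of scope. The detector assumes one straight
fiber per strip and will not segment crossing fibers or full microscope
fields. The TIFF support covers exactly the subset the renderer writes
(16-bit, 3 samples per pixel, uncompressed, little-endian). Statistical
comparison is a single pairwise contrast; no multiple-testing correction is
provided.
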