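---
title: "Spectral motion phenotyping of embryos: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral motion phenotyping of embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoflow)
```

## The problem and the model

Embryos move in ways that defeat classical trajectory-based motion analysis:
they flex, spin, twitch and pulse inside an egg capsule without net forward
displacement. This package quantifies such movement holistically, in four
stages:

1. **Sparse optic flow.** Shi-Tomasi corner features are detected on each
   frame and registered frame to frame with iterative pyramidal Lucas-Kanade
   matching. Features whose displacement-magnitude variance over a trailing
   window is high are probably not locked onto one physical point and are
   rejected.
2. **Flow decomposition.** Because embryos are gelatinous and
   shape-deformable, the flow field is encoded as directed rotations rather
   than a single rigid transform. For each frame transition we report the
   mean clockwise angular displacement of features about the feature
   centroid (`pos_angle`), the mean anti-clockwise magnitude (`neg_angle`),
   and the centroid's own displacement in polar form (`com_rho`,
   `com_theta`). Screen coordinates have y pointing down, and "clockwise" is
   defined as it appears on screen.
3. **Spectral fingerprinting.** Each of the four series is mean-centred and
   passed through the DFT; coefficient energies `(2/N^2)|X_k|^2` are summed
   over period-range bins (seconds). Binning by absolute period makes
   individuals recorded at different frame rates comparable. The binned
   energies, `log(x+1)`-transformed, form one feature vector per individual
   (72 values for an 18-bin preset, 120 for the 30-bin preset).
4. **Multivariate comparison.** Individuals are compared with Bray-Curtis
   dissimilarity; groups are tested with ANOSIM permutation tests and
   visualized with non-metric MDS.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fps` | caller-supplied | true acquisition rate (Hz); container metadata is never trusted |
| `max_features` | 400 | cap on detected corners |
| `quality` | 0.01 | relative corner-response threshold |
| `min_distance` | 5 px | minimum corner separation |
| `window` | 21 px | Lucas-Kanade integration window |
| `pyramid_levels` | 3 | coarse-to-fine levels |
| `history_window` | 15 frames | trailing window for velocity variance |
| `variance_threshold` | 4 px²/frame² | rejection threshold |
| `redetect_interval` | 50 frames | periodic feature refresh |
| `redetect_fraction` | 0.5 | refresh when retained count falls below this fraction of the last detection's yield |
| ANOSIM `n_permutations` | 9999 | Monte-Carlo draws when enumeration is infeasible |
| ANOSIM `exhaustive_limit` | 200000 | enumerate exactly below this many distinct assignments |
| nMDS `n_restarts` / `max_iter` / `tol` | 20 / 300 / 1e-7 | random restarts, iteration cap, convergence tolerance |

Two parameter choices deserve comment. The re-detection floor is a fraction
of the **last detection's yield**, not of `max_features`: scenes that
support fewer corners than `max_features` would otherwise be re-seeded on
every frame, velocity histories would never reach the three observations
the variance filter needs, and the filter would be inert. And the variance
filter never rejects a feature with fewer than three recorded
displacements, so the first ~`history_window` transitions of a record are
less protected against unreliable features than the steady state; on
10-minute recordings this warm-up is negligible.

## Frequency bin presets

Three period-range presets are built in: `DANIO_XENOPUS_18` (18 bins,
598-0.1 s), `RADIX_STAGE_18` (18 bins tuned to developmental-stage
contrasts) and `RADIX_STRESSOR_30` (30 finer bins for stressor contrasts).
Bin bounds are inclusive at both ends. Two bins of `DANIO_XENOPUS_18`
(29-20.5 s and 21-17 s) overlap on [20.5, 21]; a coefficient falling where
bins overlap or touch is assigned to the longer-period bin, a deterministic
tie-break applied uniformly. Coefficients in inter-bin gaps contribute to no
bin. Custom binsets are loadable from YAML.

The DFT convention is internal but fixed: rectangular window, DC removed,
energies `(2/N^2)|X_k|^2` for `k = 1..floor(N/2)` (the Nyquist term is not
doubled), so a unit-amplitude on-grid sinusoid carries energy 0.5 and a
gap-free binset conserves total energy exactly. No detrending beyond mean
removal is applied; no bin extends beyond the 10-minute fundamental anyway.

## ANOSIM

`R = (mean between-group rank − mean within-group rank) / (M/2)` with
`M = n(n−1)/2` pairwise dissimilarities ranked with mid-ranks, so `R` lies
in [−1, 1] and depends on the dissimilarities only through their ranks.
When the number of *distinct* group assignments — set partitions of the
individuals into groups of the observed sizes, with equal-size groups
exchangeable — is at most `exhaustive_limit`, all are enumerated and the
p-value is exact (`p = #{R_perm ≥ R_obs}/total`, observed split included);
the two-groups-of-six design typical of this assay has only 462 distinct
splits, so its p-values are exact with resolution 1/462. Larger designs
fall back to seeded Monte-Carlo with the `(+1)/(+1)` correction. Pairwise
tables carry conventional significance codes (`*** ≤ 0.001`, `** ≤ 0.01`,
`* ≤ 0.05`) and no multiplicity adjustment by default, with an optional
Bonferroni flag.

## Non-metric MDS

`nmds()` wraps vegan's global-model engine (iterative stress minimization
alternated with monotone regression on dissimilarity ranks) and adds seeded
random restarts, returning the lowest-stress solution and flagging
non-convergence. Kruskal stress-1 is reported. With near-perfectly
separable cohorts stress can approach zero slowly enough to hit the
iteration cap; the warning is informational and the best solution is still
returned.

## The synthetic-data generator

The generator exists so every stage is testable without image data.

* `synth_motion_record()` builds four-parameter series as baseline +
  sinusoids + Poisson-timed rectangular "tail-flick" bursts + Gaussian
  noise, rectified at 0 for the non-negative series. The baseline (series'
  summed oscillation amplitude + 3 noise SD) keeps the rectifier from
  half-wave-rectifying the signal, which would leak harmonic energy across
  bins; biologically it plays the role of resting motor activity.
* `synth_embryo_video()` renders a textured disc spinning and drifting
  inside a smooth, dim, static capsule ring over weak sensor noise. The
  texture is a seeded sum of Gaussian blobs evaluated **analytically** in
  the disc's moving frame, so each frame is an exact view of the
  transformed texture — no raster resampling artifacts — and the
  ground-truth motion record is known exactly. Defaults (disc radius 44 px
  in a 128-px frame, 60 blobs, capsule ring of amplitude 0.12 and width
  5 px, noise SD 0.005) emulate a well-zoomed recording where the embryo
  dominates the field; they support ≥ 50 trackable corners.
* `synth_cohort()` derives per-individual seeds deterministically from one
  master seed and attaches group labels.

What the generator does **not** emulate: non-rigid deformation (flexing,
heartbeat, blood flow), occlusion by the capsule, illumination drift, or
multiple moving objects. Passing tests therefore demonstrate that the
pipeline recovers planted rigid rotation/translation and separates planted
spectral differences — not that it is robust to every artifact of real
recordings. The capsule ring is deliberately smooth: a sharp, noisy ring
seeds hundreds of static corners that dilute the rotation means, which is
exactly the "misled by other targets" failure mode of the method; users
facing that can enable the circular ROI mask.

## Numerical and degenerate-input choices

* Untrackable transitions produce zeros, never gaps: the DFT needs complete
  series.
* Features within 1e-6 px of the centroid are excluded from rotation (their
  angle is undefined) but still contribute to the centroid.
* Angular differences are wrapped into (−π, π].
* CSV values are serialized with 15 significant digits; round trips
  reproduce records to that precision.
* Two all-zero feature vectors have undefined Bray-Curtis distance and
  raise an error naming the pair.
* Permutation comparisons use `R_perm ≥ R_obs − 1e-12` to keep exact ties
  counted under floating-point rank arithmetic.

## Problem sizes used in validation

The test-suite and acceptance fixtures use 128-px videos of 20-120 frames,
motion records of 600 s at 7.5 Hz (4500 samples, matching the 10-minute
protocol), cohorts of 6 + 6 individuals, 20 replicate cohort draws for the
power and type-I checks, 200 random series for the energy-conservation
property, and 50000 Monte-Carlo permutations against exhaustive enumeration
on 3+3, 4+3 and 4+4 designs.

## Known limitations

* Rotation means are over signed per-feature subsets, so a single
  mistracked feature can inflate the opposite-sign series for a frame;
  the variance filter suppresses this after its warm-up but not before.
* Rotation is measured about the tracked-feature centroid. If the tracked
  set includes static clutter, the centroid is biased toward it and
  rotation is underestimated; the sweep tests tolerate ≤ 10% for this
  reason.
* AVI/MP4 containers are not decoded; convert to TIFF stacks or frame
  directories.
* Bin optimization is out of scope: custom binsets are user-supplied, never
  fitted.
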