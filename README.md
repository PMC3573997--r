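# embryoflow

Holistic motion phenotyping of embryos from grayscale image sequences.

Embryos flex, spin, twitch and pulse inside their egg capsules without net
forward motion, which defeats trajectory-based behavioral analysis. This
package quantifies such movement as a *spectral fingerprint* and tests
whether treatment or developmental-stage groups differ. It is aimed at
developmental biologists and toxicologists recording multiwell time-lapse
sequences of species such as zebrafish, clawed-toad or pond-snail embryos.

## Method

1. **Sparse optic flow** — Shi-Tomasi corner features tracked with
   pyramidal Lucas-Kanade; features with high displacement-magnitude
   variance over a trailing window are rejected as mistracked.
2. **Four motion parameters per frame transition** — mean clockwise
   rotation angle of features about the feature centroid (pos), mean
   anti-clockwise magnitude (neg), and the centroid displacement in polar
   form (rho, theta). Saved to CSV as the pipeline's persistent
   intermediate.
3. **Spectral energy binning** — each series is mean-centred, DFT'd
   (energy `(2/N²)|X_k|²`), and energies are summed over period-range bins
   in seconds. Built-in presets: `DANIO_XENOPUS_18`, `RADIX_STAGE_18`
   (18 bins → 72 features per individual) and `RADIX_STRESSOR_30`
   (30 bins → 120 features). Values are `log(x+1)`-transformed.
4. **Group comparison** — Bray-Curtis dissimilarity
   `d(x,y) = Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)`, ANOSIM
   `R = (r̄_between − r̄_within)/(M/2)` with exact permutation p-values for
   small designs (a 6 + 6 design has 462 distinct splits), and non-metric
   MDS ordination (Kruskal stress-1, seeded restarts).

A synthetic-data module generates textured spinning/drifting embryo-like
videos and motion series with known ground truth, so the full pipeline is
validated without any image download.

## Worked example

Two synthetic cohorts of six embryos whose dominant rotation oscillation
differs (8 s vs 20 s period, shared moderate noise), pushed through the
spectral and statistical stages:

```r
library(embryoflow)

osc <- function(p) data.frame(series = c("pos", "neg", "rho"),
                              period_s = c(p, 13, 30), amplitude = c(1, 0.5, 0.5))
ctl <- motion_spec(duration_s = 600, fps = 7.5, oscillations = osc(8),  noise_sd = 0.3)
trt <- motion_spec(duration_s = 600, fps = 7.5, oscillations = osc(20), noise_sd = 0.3)
cohort <- synth_cohort(list(control = list(spec = ctl, n = 6),
                            stressor = list(spec = trt, n = 6)), seed = 1)

feats <- lapply(cohort$records, assemble_features, binset = preset("DANIO_XENOPUS_18"))
d <- bray_curtis_matrix(feature_matrix(feats))
anosim(d, cohort$manifest$group)
#> ANOSIM: R = 1.0000, p = 0.002165 (exact, 462 permutations) **
nmds(d, seed = 1)
#> nMDS embedding: 12 points in 2-D, stress-1 = 1.934e-06 (20 restarts)
pairwise_anosim(d, cohort$manifest$group, seed = 1)
#>   group_a  group_b R     p_value significance
#> 1 control stressor 1 0.002164502           **
```

`R = 1` means every between-group dissimilarity exceeds every within-group
one; `p = 1/462` is the smallest p-value an exact test of this design can
produce; the near-zero stress says two dimensions suffice to display the
separation. Each individual's 72-value fingerprint localizes the planted
signal: the 8-s oscillation lands in the 10-5 s bin,

```r
round(feats[[1]]$values[9:12], 3)
#> pos_angle.bin09 pos_angle.bin10 pos_angle.bin11 pos_angle.bin12
#>           0.000           0.000           0.408           0.002
```

For image data, the same pipeline starts from disk:

```r
seq <- read_sequence("embryo_A01.tif", fps = 7.5)   # TIFF stack or frame directory
rec <- analyze_sequence(seq, tracking_config())     # four motion parameters
write_motion_csv(rec, "embryo_A01_motion.csv")
```

or from the shell via the bundled CLI (`inst/cli/embryoflow.R`):

```sh
Rscript inst/cli/embryoflow.R simulate --out-dir runs --n-videos 2 --n-frames 60 --spin 0.03
Rscript inst/cli/embryoflow.R track   --fps 7.5 --out-dir runs runs/sim_01.tif runs/sim_02.tif
Rscript inst/cli/embryoflow.R spectra --fps 7.5 --binset DANIO_XENOPUS_18 \
        --out runs/features.csv runs/sim_01_motion.csv runs/sim_02_motion.csv
Rscript inst/cli/embryoflow.R compare --features runs/features.csv \
        --manifest runs/cohort_manifest.csv --out-dir runs
```

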