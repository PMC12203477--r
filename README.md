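# somatodec

Offline analysis of intracortical brain–computer interface (iBCI)
recordings from motor cortex: somatotopy mapping of per-channel movement
tuning, movement-type classification, velocity and click decoding, and
statistical comparison of decoding performance across electrode-array
locations. The package is aimed at neural-engineering researchers who want
a tested, reproducible implementation of this analysis chain, together with
a synthetic cortical-population generator so every stage can be exercised
and validated without access to human recordings.

## What it computes

Recordings are multi-unit threshold-crossing counts from two microelectrode
arrays (`medial`, `lateral`) on the precentral gyrus, binned at 50 Hz,
smoothed with a causal 440 ms exponential kernel and z-scored per channel.
On top of these rates:

* **Tuning (somatotopy mapping).** For each movement type the response
  window is 500 ms centered on the peak magnitude of PC1 of the
  trial-averaged z-scored rates (`t_M`). Per channel, Movement-window minus
  Baseline-window spike counts are tested against zero (two-tailed
  one-sample *t*-test, Bonferroni α = 0.05/4 = 0.0125), and depth of
  modulation is the signed largest rate excursion from baseline, averaged
  over trials. Per array, the proportion of modulated channels tuned to
  each movement quantifies the somatotopic gradient.
* **Classification.** Gaussian naive Bayes on Movement-window spike counts,
  full leave-one-out cross-validation, confusion matrices pooled across
  sessions (chance 25% with four movements).
* **Velocity decoding.** Per-channel linear encoding
  *f* = *b*₀ + *b*ₓ*v*ₓ + *b*ᵧ*v*ᵧ + *b*_z *v*_z + *b*_g *v*_g
  fitted with ridge regression, then inverted (indirect optimal linear
  estimation, noise-weighted) to decode 3-D translation and 1-D grasp
  velocity; performance is the squared Pearson correlation *r*² between
  predicted and actual velocities on held-out trials, compared across
  conditions (both arrays / medial only / lateral only).
* **Click decoding.** Two-state Gaussian HMM on a Fisher discriminant
  projection, Viterbi-decoded, leave-one-epoch-out (chance 50%).
* **Group statistics.** Friedman test (α = 0.05) across the three
  conditions per task, post-hoc pairwise Wilcoxon signed-rank tests at the
  Bonferroni-corrected threshold 0.05/3 ≈ 0.0167.

The synthetic generator produces populations whose tuning depths and
encoding coefficients follow a mediolateral gradient (distal movements
stronger laterally, proximal stronger medially), block-randomized
somatotopy sessions (20 blocks, 80 trials), minimum-jerk reach-and-grasp
sessions, and center-out cursor sessions with click-and-drag epochs — with
full ground truth for parameter-recovery testing. See the methods vignette
(`vignettes/methods.Rmd`) for model details and design choices.

## Worked example

```r
library(somatodec)

cfg <- generator_config()                      # 2 x 96 channels, 50 Hz
pop <- make_population(cfg, seed = 2)
ses <- simulate_somatotopy_session(pop, cfg, seed = 3)

tun <- map_tuning(ses)
proportions_by_array(tun)
classify_movements(ses)

arm <- simulate_reach_grasp_session(pop, cfg, seed = 4)
loocv_decode(arm, "medial", lambda = 1)
```

This prints (abridged):

```
  array_id movement n_tuned n_modulated proportion
1  lateral    grasp      51          54  0.9444444
3  lateral    elbow      30          54  0.5555556
5   medial    grasp      37          51  0.7254902
7   medial    elbow      46          51  0.9019608
...
LOOCV classification: 80 trials, accuracy 100.0% (chance 25.0%)

both     translation r2 = 0.718   grasp r2 = 0.871
medial   translation r2 = 0.686   grasp r2 = 0.799
lateral  translation r2 = 0.320   grasp r2 = 0.866
```

Reading it: on the lateral array 94% of modulated channels are tuned to
grasp versus 56% to elbow; medially the ordering reverses — the generated
somatotopic gradient recovered by the tuning analysis. With strong tuning
the four movements classify perfectly. Translation decodes much better from
the medial array (r² 0.69 vs 0.32), grasp slightly better from the lateral
one, and both arrays together do best — the array-location effect the
pipeline is built to quantify.

`run_pipeline(out_dir, config, n_sessions, seed)` runs every stage over
multiple sessions and writes CSV tables, figures and a manifest;
`inst/scripts/somatodec` wraps it for shell use.

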