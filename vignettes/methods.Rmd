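---
title: "Methods: somatotopy mapping and offline decoding of synthetic motor-cortex recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatotopy mapping and offline decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatodec)
```

## The analysis problem

Intracortical brain-computer interfaces record multi-unit spiking from small
electrode arrays on the precentral gyrus. Where exactly the arrays sit along
the mediolateral axis matters: hand- and wrist-related activity is expected
near the anatomical hand knob (laterally), shoulder- and elbow-related
activity more medially. `somatodec` implements the offline analysis chain
used to quantify that organisation and its consequences for decoding:

1. **Preprocessing** — binned threshold-crossing counts (50 Hz) are smoothed
   with an exponential kernel and z-scored per channel.
2. **Somatotopy mapping** — per channel and attempted movement (grasp, wrist
   extension, elbow flexion, shoulder elevation), tuning significance and
   depth of modulation against a pre-movement baseline.
3. **Movement classification** — naive Bayes on movement-window spike
   counts, full leave-one-out cross-validation, confusion matrices pooled
   across sessions (chance 25%).
4. **Velocity decoding** — per-channel linear encoding models
   `f = b0 + bx vx + by vy + bz vz + bg vg` fitted with ridge regression and
   inverted (indirect optimal linear estimation) to decode translation and
   grasp velocity; performance as squared Pearson correlation on held-out
   trials, compared across channel conditions (both arrays / medial only /
   lateral only).
5. **Click decoding** — a two-state Gaussian hidden Markov model on a Fisher
   discriminant projection, Viterbi-decoded, leave-one-epoch-out (chance 50%).
6. **Group statistics** — Friedman tests across the three conditions per
   task, with Bonferroni-corrected post-hoc Wilcoxon signed-rank tests.

Because the human recordings this kind of analysis is designed for are not
publicly released, the package ships a synthetic cortical-population
generator with a controllable somatotopic gradient. Every analysis stage is
validated against the generator's ground truth.

## The synthetic generator

`make_population()` places two 10 x 10 arrays (`lateral`, `medial`; the four
grid corners are unwired at the default 96 channels) on a mediolateral axis
`pos` in [0, 1], 0 being most lateral. A tuned channel's expected absolute
modulation depth for movement *m* is linear in `pos`:

* proximal movements (elbow, shoulder): `depth_scale * (1 + slope * (pos - 1/2))`
* distal movements (grasp, wrist): `depth_scale * (1 + slope * (1/2 - pos))`

so `gradient_slope = 0` is a flat cortex and the default 1.2 makes expected
depths vary by a factor of four across the full axis. Half of the channels
are untuned by default (`untuned_fraction = 0.5`), consistent with reports
that roughly half of recorded channels modulate with at least one attempted
movement; untuned channels carry no encoding coefficients either. Sampled
depths scatter around their expectation (gamma-distributed magnitude,
`depth_cv = 0.3`) and 15% of tuned depths are suppressive.

Encoding coefficients follow the same axis: the 3-D translation coefficient
vector has a random preferred direction with proximal-weighted magnitude,
while the grasp coefficient and the wrist-joystick cursor coefficient pair
are distal-weighted. A cursor session's `imagery` mode selects which set
drives the activity (`abstract` reach imagery uses the proximal-weighted
set, `wrist` the distal-weighted one), which is what makes the
array-condition contrasts testable.

Task structure mirrors the study conditions: somatotopy sessions run 20
block-randomized blocks of the four movements (80 trials) with Baseline 3 s,
Movement 3 s, Rest 2 s; the virtual-arm task uses minimum-jerk reach/carry
segments plus 1-D grasp open/close segments (24 trials by default, the
calibration sessions it emulates held 18-36); wrist-imagery cursor sessions
have 40 center-out trials to 8 targets; click-and-drag sessions contain 12
or 13 click-unclick epochs. The phase durations are a config knob because
the source task descriptions state both (3, 3, 2) and (2, 3, 3) s for
Baseline/Movement/Rest; the package defaults to (3, 3, 2).

Within the Movement phase, rates follow
`baseline + depth * w(t)` with `w(t)` a raised-cosine bump (0 at the phase
edges, 1 at the center). The bump shape is a design choice — the analysis
only assumes a response peak somewhere in the phase — and gives
parameter-recovery tests a well-defined target for the window center `t_M`.
Encoding-driven tasks produce z-scale drive `f + noise`, converted to rates
as `max(0, baseline + z * rate_sd)` with `rate_sd = 4` spikes/s per z-unit;
this conversion direction is never needed by the analysis itself, only by
the simulation. Counts are Poisson per 20 ms bin, or, with
`poisson = FALSE`, deterministic cumulative-rounding counts that conserve
the rate integral exactly (useful for noise-free oracle tests). During
clicked states the grasp-velocity channel carries a sustained hold drive
with smooth press/release ramps, modelling continued grasp effort; click
information therefore lives only in grasp-tuned channels, and removing the
grasp coefficients removes all click information.

Each session draws from a single RNG stream seeded by its `seed` argument,
which is recorded in the bundle: identical `(population, config, seed)`
reproduce a session bit for bit.

**What the generator does not emulate:** correlated noise across channels,
non-Poisson count dispersion, within-session nonstationarity (electrode
drift, fatigue), behavioural response-time variability in the phase onsets,
and imperfectly executed kinematics. Tests passing on this generator
demonstrate that the analysis code implements its definitions correctly and
recovers known structure — not that the same SNR or effect sizes would be
observed in real recordings.

## Numerical and statistical choices

**Smoothing.** "Exponential smoothing with a 440 ms window" underdetermines
the kernel; the package uses a causal decaying exponential truncated at
440 ms with decay constant `tau = window / 4` (110 ms, so the kernel decays
by about e^-4 across its support), normalized to unit sum. Both the window
and `tau` are exposed. Bins before the recording start are treated as
silent.

**Z-scoring.** Whole-session normalization by default (an epoch mask is
available); channels with variance below 1e-6 are flagged inactive and
excluded from PCA, classification features and decoding.

**Response windows.** PCA runs on the trial-averaged z-rates with time bins
as observations and channels as variables, over the support from 0.5 s
before Movement onset to the trial end, centered per channel. The window
center `t_M` is the peak of |PC1 score| within the Movement phase (the
absolute value sidesteps PCA's sign ambiguity), and the 500 ms window is
shifted, when `t_M` falls within 250 ms of a phase edge, to stay inside the
phase. Note the causal smoothing kernel delays the observed peak by roughly
its mean lag (~100 ms); this affects where the window lands, not the
validity of the baseline comparison.

**Tuning statistics.** The significance test uses raw window spike counts
(Movement-window total minus the 500 ms pre-Movement baseline total per
trial, one-sample two-tailed t-test, per-test alpha 0.05/4 = 0.0125), while
depth of modulation uses the smoothed rates (largest signed excursion from
the trial's mean baseline rate, averaged over trials) — counts for
detection, rates for effect size. Zero-variance deltas are degenerate:
p is set to 1, never significant.

**Classifier.** The naive Bayes emission family is not determined by the
analysis definition; the default is Gaussian per feature with a variance
floor of `1e-9 + 1e-3 * mean feature variance`, with a Poisson-likelihood
variant available since features are counts. Priors are equal (the design
is balanced) and posterior ties break to the earliest label in canonical
order (grasp, wrist, elbow, shoulder).

**Encoding and decoding.** Ridge penalties apply to slopes only. The
default penalty is chosen per LOOCV fold by inner 5-fold cross-validation
over the grid 10^-3..10^3 (a fixed-lambda mode keeps tests deterministic).
The indirect-OLE inversion is
`v = (B'WB + gamma I)^-1 B'W (f - b0)` with `W` the inverse of each
channel's encoding-residual variance, normalized to mean 1 — the
generalized-least-squares weighting implied by "optimal" linear estimation.
With homogeneous noise (including the noiseless case, where residual
variances hit a common floor) the weights are all 1 and the estimator
reduces to the plain regularized pseudo-inverse. The weighting matters in
practice: without it, pooling both arrays could fall marginally below the
better single array when one array contributes mostly noise for a given
kinematic dimension, contradicting the information ordering the analysis is
meant to exhibit. `gamma` defaults to `1e-6 * trace(B'WB) / d`. Performance
is evaluated over movement periods only, defined as bins with presented
speed above 1% of the per-trial peak; translation r^2 averages X/Y/Z (X/Y
for the cursor task) and grasp r^2 is reported separately, fitted on the
grasp/release phases.

**Cross-validation hygiene.** For the decoders, counts are smoothed per
trial (the causal kernel restarts at trial boundaries) and z-scoring
constants come from each fold's training bins only, so a held-out trial
cannot influence its own fold's model — this is enforced by a poisoning
test that corrupts a held-out trial and asserts the fold's coefficients are
bit-identical. The window finder and classifier follow the original
analysis instead: response windows are located on all trials of a session
before classification, and only the classifier itself is cross-validated.

**Click HMM.** Emissions are state-conditional Gaussians on the Fisher
discriminant projection (within-class covariance ridged by 1e-6 of its mean
diagonal before inversion); transitions are label bigram frequencies with
add-one smoothing; decoding is offline Viterbi. Evaluation is
leave-one-epoch-out with one click-unclick epoch per trial.

**Group statistics.** Friedman uses the chi-square reference (adequate for
the 18-45 sessions the comparisons target); post-hoc Wilcoxon signed-rank
tests run only when Friedman is significant at 0.05, drop zero differences,
use the exact distribution for up to 25 non-zero differences (normal
approximation with continuity correction otherwise), and are judged at
0.05/3 ≈ 0.0167.

## Verification strategy and problem sizes

Every operation is tested against an independent oracle where one exists:
smoothing against a naive O(nw) convolution loop (1e-12), the t statistic
against the mean/sd formula, ridge against a data-augmentation OLS oracle,
Viterbi against exhaustive enumeration of all 2^10 paths, Friedman against
the rank-sum formula and Wilcoxon against exact sign enumeration (1e-10),
naive Bayes against both a closed-form likelihood-ratio rule and an
independent reference implementation. Statistical properties use seeded
simulations: the tuning test's type-I error is checked at 0.0125 over
10,752 null channel-movement pairs; detection power for |depth| = 10
spikes/s on a 10 spikes/s baseline with 20 trials per movement exceeds
0.95 (Monte-Carlo reference ~0.998); chance-level behaviour of the
classifier (25% over 400 pooled null trials) and click decoder (50% on
grasp-silent sessions) sits inside 99% binomial bands; and the
array-condition ordering (translation: medial > lateral; grasp: lateral >
medial; both >= each) holds in at least 95% of 20 seeded populations of
2 x 48 channels. Test simulations use reduced channel counts and block
numbers wherever the assertion does not depend on the full 2 x 96-channel,
20-block geometry; the sizes above are the ones the assertions actually use.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config()
pop <- make_population(cfg, seed = 2)
ses <- simulate_somatotopy_session(pop, cfg, seed = 3)

tun <- map_tuning(ses)
proportions_by_array(tun)
plot(tun)                      # per-array depth heatmaps with significance

classify_movements(ses)        # LOOCV confusion matrix

arm <- simulate_reach_grasp_session(pop, cfg, seed = 4)
loocv_decode(arm, "medial")    # translation/grasp r2 for one condition

run_pipeline("report", config = cfg, n_sessions = 5, seed = 1)
```

## Known limitations

* The generator's independence assumptions (Poisson counts, uncorrelated
  channels, exact phase timing) make detection easier than in real
  recordings at matched depth; recovery rates here are upper bounds.
* Whole-session z-scoring is one defensible reading; per-block or per-trial
  normalization would change tuning results on drifting data.
* The decoders are offline: no causal filtering, no closed-loop adaptation.
* The Friedman chi-square approximation is coarse below ~5 sessions; the
  pipeline requires at least 3.
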