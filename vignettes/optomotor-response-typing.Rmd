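---
title: "Quantifying optomotor responses and discovering response types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optomotor responses and discovering response types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomotr)
```

## The measurement

A tethered insect walking on an air-supported trackball turns to follow
wide-field visual motion — the optomotor response. In the open-loop paradigm
this package analyzes, translating vertical sine-wave gratings are shown in
10-s epochs, first leftward, then instantly switching rightward, the pair
repeated four times: 80 s of stimulation per stimulus, split into 8 replicate
epochs (4 per direction). A battery of gratings varies temporal frequency
(4–48 Hz at 0.0625 cpd) and spatial frequency (0.5–0.0039 cpd at 16 Hz);
pattern angular velocity is their ratio (deg/s). Stimuli are presented in a
seeded pseudo-random order with a 3-min inter-stimulus interval.

Ball rotation is tracked per video frame (FicTrac-style 25-column logs). The
animal's integrated heading is unwrapped and signed so leftward
(counter-clockwise) turning is positive. At each direction switch, time and
accumulated rotation are reset to zero, yielding one *replicate path* per
epoch.

## The five response features

For each animal × stimulus response (8 replicate paths):

* **Maximum accumulated rotation (`ymax`)** — rightward paths are
  sign-inverted so both directions are on a common positive scale; the peak
  of each corrected path is averaged per direction (`ymax_l`, `ymax_r`) and
  `ymax` is their mean. We take the *peak* of the path rather than its
  terminal value, since a response that overshoots and then wavers back
  should be credited with the rotation it actually produced.
* **Rotation asymmetry** — `y.sym = |ymax_r − ymax_l| / max(ymax_r, ymax_l)`,
  0 for symmetric responses, 1 for fully one-sided ones. When both direction
  averages are exactly 0 the ratio is 0/0; we define `y.sym = 0` there (a
  symmetrically absent response) and flag the row `degenerate_asymmetry`.
* **Tortuosity** — each replicate path is fit by ordinary least squares of
  accumulated rotation on time; tortuosity is the mean R² across the 8 fits.
  Prompt, sustained turning gives R² near 1; wavering or slow switching gives
  low values. The fit includes an intercept by default (`fit_intercept`):
  a reaction latency shifts the linear portion of the path off the origin,
  and forcing the line through 0 would conflate latency with tortuosity.
* **Absolute turning velocity** — the *signed* replicate slopes are averaged
  first and the absolute value taken second, so symmetric responses cancel
  to 0 and only a consistent turn bias survives.
* **Walking pace** — per-frame total ball rotation magnitude (norm of the
  three-axis rotation increment) × ball radius, summed and divided by
  stimulation time, averaged over the 8 epochs; cm/s. If the three-axis
  increments are missing, the tracker's movement-speed column is used.

Ties in the bias direction are broken at 1e-9 rad (`NONE` below that);
replicates with fewer than 3 frames are dropped from all means, and a
stimulus with fewer than 2 valid replicates per direction is flagged
`low_confidence`.

## Discovering response types

Features are pooled across treatments and stimuli, rows with undefined
features removed, and columns z-scored (sample SD). Response types are then
found by subsampled k-means consensus clustering: each of `reps` iterations
clusters 90% of the responses and 80% of the features (4 of 5), and the
fraction of iterations in which two responses co-cluster — given both were
sampled — forms the consensus matrix.

Stability per candidate k is the **proportion of ambiguous clustering
(PAC)**: the fraction of off-diagonal consensus entries strictly inside
(0.1, 0.9). To decide k, the same procedure runs on Monte-Carlo reference
data: structureless multivariate-normal surrogates whose covariance equals
the real data's empirical covariance (equivalently, simulation in the
empirical principal-component basis), so feature correlations alone cannot
masquerade as clusters. The **relative cluster stability index**

$$\mathrm{RCSI}(k) = \ln\frac{\overline{\mathrm{PAC}}_{\mathrm{null}}(k)}
{\mathrm{PAC}_{\mathrm{real}}(k)}$$

is maximized over k (PAC values floored at 1e-4 before the ratio, since a
perfectly stable clustering has PAC exactly 0); a per-k p-value comes from a
normal approximation to the null PAC spread. Final labels are the
average-linkage hierarchical cut of the consensus dissimilarity `1 − M` at
the chosen k, renumbered by descending cluster size.

Numerical choices: k-means uses the stock Hartigan–Wong algorithm with 5
random restarts per subsample (`nstart`, configurable). With a couple of
hundred subsampled iterations per k, the consensus matrix aggregates away
per-run initialization differences, and restarts beyond a handful change
third-decimal PAC values at several times the cost; the k range (2–10), PAC
window, and floor are likewise exposed as arguments.

## Group statistics and dose arithmetic

Treatment comparisons of consumption-style or spontaneous-behavior tables
use Kruskal–Wallis rank-sum tests (tie-corrected H, chi-square reference on
g−1 df, with an optional Monte-Carlo permutation p-value preferable below
n ≈ 10 where the chi-square approximation is rough), Mann–Whitney U post
hocs (exact enumeration when tie-free and `n_a·n_b ≤ 400`, else normal
approximation with tie-corrected variance and continuity correction), and
Bonferroni adjustment over the family of comparisons actually performed.

Exposure arithmetic treats ppb as ng of active ingredient per mL of feeding
solution: `ppb_to_nanomolar(conc, mw) = conc·1000/mw` and
`daily_dose(volume_ul, ppb) = volume·ppb/1000` ng/day. Reported molarities
conventionally quote the integer part. A mixture of two compounds at half
concentration each receives half of each daily dose; computing such values
from first principles can differ in the last digit from tables that halve
rounded numbers.

## The synthetic cohort generator

Real trackball data are large and lab-specific, so validation runs on a
ground-truthed generator. Each animal is a kinematic archetype: per frame,
heading increment = (direction signal delayed by a reaction latency) × gain
+ turn bias + Gaussian rotational noise, Euler-integrated at the frame rate
(default 50 Hz); forward walking turns the ball about its pitch axis at
pace/radius. Noise scales with √dt so feature statistics are
frame-rate-invariant. Three archetypes span the response space:

| archetype | gain (rad/s) | latency (s) | bias (rad/s) | pace (cm/s) | noise (rad/√s) |
|---|---|---|---|---|---|
| FOLLOWER | 0.5 | 0.5 | 0.02 | 1.0 | 0.15 |
| BIASED_TURNER | 0.1 | 1.0 | 0.6 | 2.5 | 0.20 |
| SHALLOW_WALKER | 0.04 | 1.5 | 0.06 | 0.8 | 0.12 |

FOLLOWER produces robust, symmetric, low-bias responses (high `ymax`, R² ≈ 1,
`y.sym` ≈ 0.1); BIASED_TURNER turns fast and one-sidedly regardless of
stimulus (`y.sym` ≈ 1, high turning velocity and pace); SHALLOW_WALKER mostly
walks forward with low-magnitude, noisy turning (low `ymax` and R²). These
parameter values are free synthetic choices tuned once so the archetypes are
separable at the feature level with realistic within-type spread; bias sign
is drawn ± per animal and gain/bias/pace receive lognormal per-animal jitter
(CV 0.12).

The default cohort has four treatments (one control, three exposure groups;
22/25/28/25 animals) over the 12-stimulus battery — 1200 responses. The
control mixes archetypes 70/15/15 and the exposure groups roughly 20/45/35
toward the two impaired types; these mixing proportions are again synthetic
choices that qualitatively reproduce a control dominated by robust followers
and treatments dominated by impaired response types.

What the generator does **not** emulate: stimulus-dependent gain tuning
(real optomotor gain falls off at extreme spatio-temporal frequencies,
whereas an archetype here behaves identically across the battery),
within-session drift or fatigue, tracking artifacts, and any closed-loop
dynamics. Passing the recovery tests therefore shows the *pipeline* is
correct and stable, not that three clusters exist in any particular real
data set.

## Problem sizes and determinism

The shipped validation runs use 200 consensus iterations per k and 25
reference datasets on the 1200-response default cohort; unit tests use
smaller cohorts and 40–200 iterations. The consensus stage at its published
scale (2000 iterations) is a single argument change. Every stochastic
function takes a seed; cohorts, consensus matrices and pipeline outputs are
bit-reproducible given one.

```{r example, eval = FALSE}
design <- default_design()
features <- cohort_features(design)
Z <- zscore_features(features)
ks <- select_k(Z, k_range = 2:10, reps = 200, B = 25, seed = 1)
ks$chosen_k   # 3
labels <- assign_clusters(consensus_run(Z, ks$chosen_k, reps = 200, seed = 2),
                          ks$chosen_k)
cluster_proportions(labels, features[attr(Z, "kept_rows"), ])
```

## Known limitations

* `align()` assumes a constant, known offset `t0` between trajectory clock
  and schedule clock; clock drift within a session is not modeled.
* Only the 25-column FicTrac v2 comma-delimited dialect ships; the dialect
  registry is the extension point for others.
* The beta/GLMM modelling layer often applied downstream of these features
  (mixed models over repeated measures, post hoc contrasts) is out of scope;
  the exported tables are designed to feed such tools directly.
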