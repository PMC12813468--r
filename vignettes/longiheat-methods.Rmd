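---
title: "Methods: simulating, encoding and classifying longitudinal brain features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, encoding and classifying longitudinal brain features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longiheat)
```

# The problem

Structural MRI yields a handful of scalar biomarkers per scan session —
gray-matter (GM), white-matter (WM) and cerebrospinal-fluid (CSF) volumes,
mean cortical thickness (CT), and white-matter-hyperintensity (WMH) volume —
whose *trajectories over time* carry staging information across the dementia
spectrum: cognitively normal (CN), early and late mild cognitive impairment
(EMCI, LMCI), undifferentiated MCI, and Alzheimer's disease (AD). `longiheat`
implements a pipeline that

1. represents each subject's longitudinal feature series as a small image — a
   28-bin time heatmap with value, rate-of-change and availability channels,
   quantized at a chosen bit depth;
2. classifies those heatmaps into the five diagnostic groups with a compact
   CNN and a fully convolutional network (FCN);
3. localizes, via Grad-CAM, *when* in the trajectory the classifier found its
   evidence; and
4. compares groups with a nonparametric statistical protocol
   (Shapiro–Wilk screening, Kruskal–Wallis omnibus tests, Benjamini–Hochberg
   adjustment, Dunn post-hoc contrasts).

Real cohorts of this kind are access-restricted, so the package ships a
synthetic-cohort generator parameterized by published per-group summary
statistics. Everything downstream is developed and tested against it.

# The synthetic cohort generator

## What it emulates

Each diagnostic group has a generative profile holding, per feature, a
baseline distribution (mean, SD), an annual-change distribution (median, IQR,
and the fraction of subjects whose feature increases), and physical
plausibility bounds; plus subject counts (22 AD, 22 CN, 25 MCI, 20 EMCI,
25 LMCI — 114 in total), session-count ranges and follow-up windows, and a
TIV distribution. A subject is simulated as

$$x_f(t) = b_f + s_f \cdot t/12 + \varepsilon_f(t),$$

with $t$ in months, baseline $b_f$, annual slope $s_f$, and per-visit
Gaussian noise $\varepsilon_f$, clipped to the feature's plausible range.
Visit schedules are irregular: the session count is uniform over the group's
range, inter-visit gaps are uniform on [3, 12] months (3 months is the bin
width of the encoder, so finer spacing would be invisible), and visits
beyond the group's follow-up ceiling are dropped.

## The slope distribution

The published change statistics constrain three things at once — the median,
the IQR, and the sign fraction (e.g. AD CSF: median +14.61 ml/yr, IQR
+9.57 to +16.42, 14/15 subjects increasing). A two-piece distribution centred
on the median with scales fitted to the quartiles would fix the median and
IQR but leave the sign probability implied (for AD CSF it would imply
97.5% increasing rather than 93.3%). We therefore construct the slope
distribution directly as a **piecewise-linear quantile function** anchored at

- $(0.25,\ q_{25})$, $(0.5,\ \mathrm{median})$, $(0.75,\ q_{75})$,
- $(1 - f_{\uparrow},\ 0)$, where $f_{\uparrow}$ is the published fraction
  increasing, and
- Tukey-whisker tails, $q_{25} - 1.5\,\mathrm{IQR}$ at $p = 0.01$ and
  $q_{75} + 1.5\,\mathrm{IQR}$ at $p = 0.99$, with uniform draws clamped to
  $[0.01, 0.99]$ so the support is bounded.

All four published constraints then hold *exactly* in distribution. When
$f_{\uparrow} = 1$ (every subject increases) the lower tail is truncated just
above zero instead.

Annual-change parameters for GM, WM and CT are published only qualitatively,
and the direction stated for GM is internally inconsistent between groups.
The defaults encode the standard neurodegeneration convention — GM/WM loss
and cortical thinning whose magnitude grows with disease stage — and are
ordinary list fields on the profile objects, so any other convention is one
assignment away rather than a hidden constant.

## Other generator choices

- **WMH baselines are lognormal**, moment-matched to the published mean/SD.
  WMH volumes are non-negative and strongly right-skewed (AD mean 8.22 ml,
  SD 12.8 ml); a Gaussian would put ~26% of baselines below zero and clipping
  would destroy the published moments. All other features use Gaussians.
- **Plausible ranges are physical bounds** (e.g. CT in [1.2, 3.6] mm, WMH in
  [0, 150] ml), not the observed min–max of any particular cohort. Clipping
  to observed ranges of ~100 scans would visibly bias the generative moments;
  physical bounds almost never bind, so parameter recovery stays clean while
  impossible values (negative volumes) remain impossible.
- **TIV** is constant within subject, drawn from N(1500, 120²) ml — typical
  adult intracranial volumes; the source tables do not report a TIV
  distribution.
- **Per-visit noise** defaults to 5% of the feature's baseline SD. No
  residual model is published; 5% keeps within-subject scatter visibly
  smaller than between-subject scatter, as in real volumetric pipelines.
- **Features are independent channels.** Real biomarkers co-vary within
  subject; modelling that correlation is out of scope, and passing tests on
  this generator therefore says nothing about exploiting (or being confused
  by) cross-feature correlation in real data.
- **Determinism.** Every subject gets an RNG substream derived from the
  master seed, the group code and the subject index, so cohorts are
  reproducible byte for byte and independent of generation order.

One consequence of simulating honestly: per-subject OLS slope estimates from
3–4 noisy visits are themselves noisy, and convolving a left-skewed slope
distribution with symmetric estimation noise pulls the *estimated* median
slightly toward the mean. Recovered AD CSF medians land around 13.3–14.2
ml/yr against the generating 14.61 — within three Monte-Carlo standard
errors, which is exactly the tolerance the recovery checks use.

# Heatmap encoding

The time axis is 0–84 months in 28 half-open 3-month bins $[3k, 3k+3)$, with
a scan at exactly 84 months joining the last bin. Three channels per feature:

- **C1 (value):** per-bin mean of the session values (multiple scans in one
  bin are averaged), min–max scaled to [0, 255] via
  $f_z = (f - f_{\min})/(f_{\max} - f_{\min}) \times 255$ and quantized to
  $2^b$ levels, $b \in \{2, 3, 4, 8, 16\}$, by snapping to
  $\mathrm{round}(x/255\,(L-1)) \cdot 255/(L-1)$.
- **C2 (rate):** the slope between consecutive *occupied* bins at bin-center
  times, in units per month, min–max scaled; the first occupied bin is 0.
- **C3 (mask):** 1 where a scan exists, 0 otherwise — kept binary at every
  bit depth so the models can tell "missing" from "no change". C1 and C2 are
  forced to 0 wherever C3 = 0.

Numerical conventions worth stating:

- **Normalization scope.** $f_{\min}, f_{\max}$ are computed on the training
  split only and frozen for test encoding, so the representation leaks no
  test information. Degenerate ranges ($f_{\max} = f_{\min}$) map to all
  zeros; out-of-range test values clip to the ends.
- **The rate normalizer.** The source description of C2 divides the slope by
  a total study duration T = 180 months, but its formula is typographically
  garbled and 180 months exceeds the 84-month axis; a constant positive
  divisor also cancels in min–max scaling, so it cannot change what a model
  sees. The default is the raw inter-visit slope; `rate_channel(...,
  total_T_months = 180)` enables the normalized reading.
- **Channel count.** The narrative description says two channels but defines
  three and the classifier input is three-channel; three is implemented.
- Sessions after month 84 are outside the representable window and are
  dropped with a warning at encoding time (long-follow-up groups do reach
  past it).

# Classifiers

Both networks consume the `1 × 28 × 3` heatmap. Since the height is 1, the
nominal 3×3 kernels and 2×2 pools act along time only: width-3 convolutions
with same padding, and 1×2 max pooling (a literal 2×2 pool is undefined on a
height-1 grid; 1×2 preserves the spatial-reduction intent).

- **CNN:** conv 32 → pool → conv 64 → pool → flatten → dense 128 (ReLU) →
  dense 5 + softmax.
- **FCN:** conv 32 → pool → conv 64 → pool → conv 128 (bottleneck) →
  upsample → conv 64 → upsample → conv 32 → 1×1 conv to 5 classes with a
  per-bin softmax, restoring the 28-bin width. The input is three-channel
  (one stated shape in the source says four; three is consistent with the
  encoder and the CNN). The subject-level prediction is the mean of the
  per-bin probability vectors; training broadcasts the subject label to all
  bins, optionally weighting each bin's loss by the availability mask
  (`mask_loss = TRUE`; off by default, as no masking is described).

Training follows the stated protocol: Adam (learning rate 0.001), batch size
32, sparse categorical cross-entropy, 70 epochs for the CNN and 50 for the
FCN, after a subject-level stratified 80:20 split. Weights are
Glorot-uniform, seeded. There is no early stopping and no augmentation.
The whole engine is plain R matrix arithmetic with hand-derived backprop,
verified against central finite differences in the test suite; training is
bit-reproducible for a fixed seed, and sorting samples by a caller-supplied
key makes it invariant to input order too.

# Grad-CAM

For a target class, the gradient of its pre-softmax score with respect to
the last convolutional layer's activations is averaged over time positions
to weight each filter; the ReLU of the weighted activation sum is min–max
normalized to [0, 1] and linearly interpolated from the conv grid (14
positions for the CNN) back to 28 bins, aligning bin centers. Maps explain
the *predicted* class by default; any class can be requested. For the FCN
the subject-level score is the bin-mean logit and attribution is taken at
the last decoder convolution. Group profiles average members' maps
element-wise (by true group membership) and renormalize.

The randomized-weights sanity check re-initializes the architecture and
reports the mean per-sample Spearman correlation between trained-model and
random-model maps, with a sign-flip permutation p-value. Because the
activations of even a random network reflect input magnitudes, this
correlation need not vanish — the meaningful reference is the trained-vs-
retrained correlation, which the checks compare against.

# Group statistics

The analysis is session-level: descriptives (mean, sample SD), Shapiro–Wilk
normality per group × measure, and Kruskal–Wallis omnibus tests per measure
with $\chi^2_{k-1}$ reference. WMH is tested on the $\log(1+x)$ scale —
though, being strictly monotone, the transform provably cannot change any
rank-based result, which the tests verify. Pairwise post-hoc contrasts use
Dunn's tie-corrected z statistics with BH adjustment (the source does not
name its post-hoc; Dunn is the standard companion to Kruskal–Wallis and is
flagged here as a package assumption). Session-level testing treats repeated
scans as independent, which inflates type-I error under within-subject
correlation; `group_stats_report(..., by_subject = TRUE)` is the
subject-mean sensitivity mode. Cortical thickness is analyzed in mm,
unnormalized — expressing a thickness "relative to TIV" (as one source table
header suggests) has no physical meaning.

# Problem sizes and tolerances in the checks

The automated checks run at sizes chosen to make their statistics decisive
yet quick: parameter recovery at 500 subjects per group (3 Monte-Carlo SEs);
null rejection rates of Shapiro–Wilk and Kruskal–Wallis at 2,000 replicates
(±3 binomial SEs around 5%); end-to-end classification on a deliberately
separable cohort (group means 5 within-group SDs apart, 150 subjects,
full 70/50-epoch budgets) with a mask-aware nearest-centroid oracle and a
label-permuted control expected at 5-class chance; Grad-CAM localization on
100 synthetic heatmaps whose group signal lives only in bins 1–10.

# Limitations

- The generator's linear-trajectory, independent-feature model cannot show
  whether the classifiers exploit nonlinear progression or cross-marker
  coupling in real data; accuracy on the *default* synthetic cohort is far
  below published real-data figures, as it should be — the published
  group SDs overlap heavily at baseline, and the synthetic cohort contains
  no information beyond those summary statistics.
- The 84-month window discards later sessions rather than re-binning.
- The statistics layer implements the nonparametric branch only; covariate-
  adjusted GLMs (age, sex, site) are out of scope.
- Heatmaps are per-feature; multi-feature fusion models are not provided.
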