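---
title: "Methods: movement-pattern analysis of running gait waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement-pattern analysis of running gait waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis model

`gaitpattern` treats one running cycle as a single point in a
high-dimensional movement space. Each trial contributes nine sagittal-plane
angle waveforms — foot, ankle, knee, hip, pelvis, spine, thorax, neck, head —
sampled over one cycle, time-normalized to 201 equidistant points spanning
0–100% of the cycle inclusive, and concatenated in that fixed order into one
row of the feature matrix $M$ (9 × 201 = 1809 columns). Rows are trials from
all subjects, conditions and sides; left and right cycles are separate rows
with identical column layout (no mirroring), because sides are compared
through the symmetry index rather than pooled.

Standardization subtracts the per-column mean over all rows and divides each
*variable set* — one angle's 201-point block — by a single pooled scale, the
sample standard deviation of all centered entries of the block. After this,
every variable set of $M'$ has zero mean and unit pooled standard deviation
while the *relative* variability across the cycle (e.g. high mid-swing knee
variability versus low stance variability) is preserved. Dividing each
column by its own SD would flatten exactly that time-dependent structure,
which downstream stages rely on; a per-column mode is nevertheless available
(`standardize(..., sd_mode = "column")`) for sensitivity analyses. The
standardization is affine and invertible: `inverse_standardize()` maps any
profile — a group mean, a discriminant direction — back to degrees, which is
what makes discriminant back-projection possible.

The assumptions are the usual ones of waveform-level gait analysis: cycles
are segmented correctly upstream (the pipeline starts from per-cycle series;
event detection, gap filling and smoothing are out of scope), 201 points
resolve the angular dynamics of running, and amplitude information on the
common time base carries the signal (no time warping).

### Clustering

K-means with the squared-Euclidean objective gives the first, unsupervised
picture. Initial centers use spread-out (kmeans++-style) seeding under a
fixed seed, the best of `restarts` runs by inertia is kept, so results are
reproducible; adding restarts can only lower the best inertia. The number of
clusters is chosen by the highest mean silhouette over a candidate range
(default 2–40, so a solution near a typical cohort's subject count is
interior to the scan); ties break toward the smaller K and the chosen K is
logged. A best mean silhouette below 0.25 triggers a warning, following the
usual reading of silhouette values below that level as "no substantial
structure". Silhouettes use Euclidean distance; rows in singleton clusters
get width 0 by convention. Loading rates then quantify how concentrated each
group of trials is: for a grouping (subject, condition, or
subject × condition × side), a group's rate in a cluster is its trial count
there divided by its total; rates sum to 1 per group and the per-group
maximum is the reported summary. The merge tree uses Ward linkage by
default, consistent with the K-means variance objective; single, complete
and average linkage are available, and the tree exports as Newick text.

### Classification

Each pairwise comparison trains a maximal-margin linear separator (SVM,
linear kernel) and evaluates it leave-one-out: train on all rows but one,
predict the held-out row, accumulate. The margin penalty defaults to
`cost = 1`; at these row/column ratios (tens of rows, 1809 columns) the
groups are typically separable and the linear-kernel solution is insensitive
to the exact penalty, but the value is exposed for reproducibility. A
decision value of exactly zero predicts the first (reference) group, making
the procedure fully deterministic. Significance uses the exact one-sided
binomial criterion: the smallest correct-count whose upper tail probability
under chance 0.5 is at most α = 0.05. The critical count is derived from the
actual per-comparison row count, so comparisons with unequal trial numbers
get their own thresholds; below n = 5 no count can reach significance and
the result is reported as non-significant with a missing critical count.

The three schemes mirror the scientific questions: subject vs subject (all
pairs — are movement patterns individual?), condition vs reference pooled
across subjects (is there a subject-independent condition signature?), and
condition vs reference within each subject (does the condition change the
individual's pattern?). The leave-one-out unit is one row — one trial-side
waveform — and both sides of a subject enter the within-subject comparisons.

For a significant comparison the discriminant weight vector is extracted
from the fitted separator, normalized to unit length, and the variables with
$|w_i| > 2\,\mathrm{SD}(w)$ are selected as the movement features driving
the separation (for standard-normal weights this selects about 4.6% of
variables, so selections well above that fraction indicate concentrated
structure). Because standardization is affine, group means and the
discriminant direction are mapped back to degrees and reshaped per angle.

### Symmetry

The symmetry index per subject × condition compares the mean right-side
waveform with the mean left-side waveform over the full 1809-point layout:
the difference at each time point is divided by the pooled standard
deviation of the two sides at that point (equal-weight pooling,
$\sqrt{(s_L^2 + s_R^2)/2}$, with no weighting stated for unequal trial
counts), the normalized differences are *summed with sign*, and the absolute
value is taken. The signed sum follows the index's definition literally; it
allows cancellation between time points, so a systematic offset asymmetry
registers strongly while a zero-mean shape difference can cancel.
`sum_mode = "absolute"` computes the non-cancelling variant for comparison.
Time points with pooled SD below 1e-9 are excluded with a warning to avoid
division blow-ups on degenerate (noise-free synthetic) inputs; at least two
trials per side are required for the pooled SD to exist.

### Statistics

Condition effects on the symmetry index use the tie-corrected Kruskal-Wallis
rank-sum test (the index is not assumed normal). The gender subgroup
analysis runs a Friedman test within each sex (complete subject × condition
blocks) and a between-sex Mann-Whitney test per condition, with the
normal-approximation Z (tie-corrected, no continuity correction) and the
Rosenthal effect size $r = |Z|/\sqrt{N}$ labelled at the 0.1 / 0.3 / 0.5
thresholds; it is a secondary analysis and is reported without alpha
correction. Running speed, which is plausibly normal, is checked with a
Lilliefors normality test, a one-way repeated-measures ANOVA on per-subject
condition means, and paired t-tests under Holm correction; when the
per-subject condition means are exactly equal the ANOVA p-value is 1 by
definition rather than 0/0.

## The synthetic cohort generator

The generator exists so that every stage can be validated against known
ground truth. Each angle waveform of a trial is a sum of smooth cyclic
components:

* a fixed population template per angle, loosely shaped like sagittal
  running kinematics (large knee/hip excursions, small trunk and head
  motion); any smooth template would do — no physiological fidelity is
  claimed;
* a per-subject random offset, scale `sigma_subject` = 4° — between-subject
  differences in running style are of this order and dominate all other
  components, which is what makes movement patterns individual;
* a per-subject × condition perturbation, scale `delta_cond` = 1° — the
  small but trial-consistent effect of a condition on that subject;
* a side asymmetry added to the right side only (the index uses only the
  side *difference*, so which side carries it is irrelevant), with magnitude
  `alpha_neutral` = 1.5° in the reference condition and `alpha_splint`
  = 0.5° otherwise, making the reference condition the least symmetric;
* trial-to-trial noise, scale `sigma_trial` = 0.75° — within-subject cycle
  variability of a practised movement is below a degree.

All random components are low-order Fourier series (default 4 harmonics)
rather than white noise, so trial noise is as smooth as real time-normalized
kinematics. Scales are calibrated so each component's pointwise standard
deviation equals its scale parameter exactly. The subject, condition and
asymmetry components include a constant (DC) Fourier term: a purely
zero-mean cyclic asymmetry integrates to nearly zero over the cycle and
would be invisible to the signed-sum symmetry index, whereas real asymmetry
typically includes a consistent offset (one limb habitually more flexed).
Sex labels (about one quarter female) and condition-independent running
speeds (≈ 3.2 ± 0.25 m/s between subjects, 0.05 m/s trial jitter) are
attached as metadata for the subgroup and speed analyses. `drop_trials()`
thins a cohort uniformly at random while protecting one trial per
subject × condition × side cell, emulating real post-exclusion missingness.

What the generator does *not* emulate: inter-segment coupling (angles are
drawn independently), phase (timing) differences between conditions or
sides, speed-kinematics covariation, non-stationary drift across a session,
and any biomechanical constraint linking the nine angles. Passing tests on
synthetic cohorts therefore demonstrate that the algorithms recover the
variance structure they target — not that real splint effects have the
simulated form or size. With the default scales the simulated condition
effect is deliberately strong enough to be recovered reliably within
subjects; chance-level behaviour is exercised separately by setting
`delta_cond = 0`.

## Numerical choices

* **Interpolation**: cubic spline on the normalized time axis for series of
  ≥ 4 samples (upstream data are spline-smoothed, so a smooth interpolant is
  appropriate), linear for shorter series; endpoints are preserved exactly.
* **Pooled block SD**: the sample SD of all centered entries of a block,
  denominator $201\,n - 1$; blocks with SD below 1e-12 raise a
  degenerate-data error rather than producing infinities.
* **K-means**: Hartigan-Wong iterations from kmeans++-style starts;
  `k = n` rows is the exact singleton solution (inertia 0) by definition.
* **Determinism**: every randomized stage takes an explicit seed and
  restores the caller's RNG state; reruns of the full pipeline with the same
  configuration are byte-identical.
* **Ties**: silhouette-K ties go to the smaller K; zero decision values
  predict the reference group; Holm decisions use the literal step-down.

## Problem sizes used in the checks

The packaged checks validate identities and oracle equivalence at small n
(exhaustive K-means partitions at n ≤ 16, rank-test enumeration at n ≤ 8,
binomial tails at n ≤ 60) and parameter recovery on cohorts of 3–6 subjects
with 2–3 trials per cell over ten or more seeds; the acceptance script runs
the full pipeline on a 10-subject × 4-condition × 3-trial × 2-side cohort
(240 × 1809). These sizes were chosen to exercise every stage, including the
silhouette scan and all three classification schemes, at a scale a desk
machine reproduces in minutes; the statistical properties being checked
(chance-level nulls, monotone recovery, subject concentration) are
scale-free.

## Known limitations

* The deposited cohort of the original splint study is distributed as a
  split binary archive; reproducing its published numbers requires
  downloading and converting it to the trials CSV layout (see the acceptance
  test), which this package does not automate.
* The linear-margin penalty is fixed, not tuned; with tens of rows in 1809
  dimensions the groups are usually separable and the choice is benign, but
  very unbalanced or noisy comparisons may be sensitive to it.
* The signed-sum symmetry index is cancellation-sensitive by construction;
  results should be read alongside the absolute-sum variant when shape
  (rather than offset) asymmetry is of interest.
* Condition labels are free strings with one designated reference; analyses
  assume the reference condition is present in every subject.
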