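# gaitpattern

Pattern-recognition analysis of single-cycle running kinematics in R.

Movement scientists often ask whether an intervention — footwear, an
orthosis, a dental splint — changes how a person runs, when the change is
far smaller than the differences between runners. `gaitpattern` implements
the vector-based analysis used for that question: each trial is one running
cycle described by nine sagittal-plane angle waveforms (foot, ankle, knee,
hip, pelvis, spine, thorax, neck, head), time-normalized to 201 points and
concatenated into one row of a trials × 1809 feature matrix *M*. The matrix
is standardized per *variable set* (one angle's 201-point block):

```
M'_j(k) = ( M_j(k) − mean(M(k)) ) / SD{M(k)}
```

with the mean taken per column over all trials, conditions, sides and
subjects, and one pooled SD per angle block so the time-dependent shape of
the variability is preserved. On *M'* the package runs:

* **Clustering** — K-means (squared-Euclidean objective, spread-out seeding,
  best of restarts) with the number of clusters chosen by the highest mean
  silhouette; per-group cluster *loading rates* (fraction of a subject's,
  condition's, or subject×condition×side cell's trials in one cluster);
  Euclidean distance matrix and Ward merge tree (Newick export).
* **Classification** — pairwise leave-one-out classification with a linear
  maximal-margin separator (SVM) in three schemes: subject vs subject,
  condition vs reference pooled across subjects, and condition vs reference
  within each subject. A classification rate `r_class` is significant when
  the number of correct predictions reaches the exact one-sided binomial
  critical count (chance 0.5, α = 0.05). For significant comparisons the
  discriminant weight vector is extracted, variables loading beyond 2 × SD
  of the weights are selected, and group means and discriminant are
  back-projected to degrees through the inverse standardization.
* **Symmetry** — a left/right symmetry index per subject × condition:
  right-side mean waveform minus left-side mean waveform, each time point
  divided by the pooled SD of the two sides, summed over all 1809 points,
  absolute value. 0 = perfectly symmetric; dimensionless.
* **Statistics** — Kruskal-Wallis across conditions, Friedman and
  Mann-Whitney (with Rosenthal effect sizes r = |Z|/√N, labelled at
  0.1/0.3/0.5) for subgroup analyses, Holm correction, and a
  repeated-measures ANOVA check that running speed does not differ between
  conditions.
* **Synthetic cohorts** — a generator of labelled running cycles with
  controllable subject, condition, side and trial variance components
  (smooth low-order Fourier waveforms), so every stage can be validated
  against known ground truth.

## Worked example

```r
library(gaitpattern)
cfg <- analysis_config(synth = synth_config(n_subjects = 6, n_trials = 3, seed = 11),
                       k_candidates = 2:12, restarts = 10, seed = 11)
report <- run_full_analysis(cfg, "demo_out")
print(report)
#> gaitpattern analysis report
#> feature matrix: 144 rows x 1809 columns
#> best k: 6 (mean silhouette 0.6781)
#> loading rates [subject]: 6/6 groups at rate 1, median max 1.000
#> loading rates [condition]: 0/4 groups at rate 1, median max 0.167
#> loading rates [subject_condition_side]: 48/48 groups at rate 1, median max 1.000
#> pairwise subjects: 15 of 15 significant
#> across-subject condition rates: Centric=0.972, DPS=1.000, Max=0.986
#> within-subject mean rates: Neutral vs Centric=1.000, Neutral vs DPS=1.000, Neutral vs Max=1.000
#> symmetry medians: Neutral=526.283, Centric=163.690, DPS=267.987, Max=93.955
#> Kruskal-Wallis: H=5.3667, df=3, n=24, p=0.1468
#> seed: 11; package version: 0.1.0
#> running speed ANOVA: p=0.5627
```

Reading the output: 144 trials (6 subjects × 4 conditions × 3 trials × 2
sides) give a 144 × 1809 matrix. The silhouette scan picks 6 clusters — one
per subject — and every subject's trials load entirely into one cluster
(rate 1), while conditions spread evenly over clusters (max rate 0.167):
runners are individual, the splint conditions are not a global signature.
All 15 subject pairs classify significantly. Within each subject the
conditions separate perfectly here because the simulated condition effect
(1°) is consistent trial to trial. The reference (Neutral) condition is the
least symmetric — its simulated asymmetry (1.5°) exceeds the splint
conditions' (0.5°) — and running speed shows no condition effect. Every
number is also written to CSV stage files plus `report.txt` under the
output directory.

The command-line wrapper exposes the same stages:

```sh
Rscript inst/cli/gaitpattern.R all --config config.yaml --out results_dir --seed 11
```

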