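---
title: "Methods: models, statistics and design choices in hfadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in hfadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hfadyn` analyses the temporal dynamics of visual representations in
intracranial EEG: how category and exemplar information carried by
broadband high-frequency activity (HFA, 70–150 Hz) evolves while a
stimulus stays on the screen, and whether the neural code that carries it
is stable or changes over time. This vignette documents the models and
statistics the package implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where a published description leaves the
implementation open.

## 1. HFA estimation

HFA is estimated per electrode from the continuous voltage by band-pass
filtering in eight 10-Hz sub-bands spanning 70–150 Hz (zero-phase FIR,
Hamming window; the order follows the standard heuristic
`3.3 / (transition width / fs)` with a 2.5 Hz transition), taking the
modulus of the analytic signal in each band, dividing each band's
amplitude by its mean over the whole recording, and averaging bands. The
per-band normalization compensates the 1/f spectrum, so each band
contributes equally; it forces each normalized band to global mean 1 and
makes the output invariant to rescaling the input. Whether the
normalization window should be the whole recording or task blocks only is
ambiguous in principle; the package normalizes over the whole trace passed
in, so callers can restrict it by slicing beforehand.

Epochs span −300 to 1600 ms around stimulus onset. Baseline correction
subtracts the mean HFA in the 300 ms before onset, per trial and
electrode, and is idempotent. Smoothing is a 50-ms centered moving
average applied *after* baseline correction; at the epoch edges the
window shrinks rather than padding, which conserves the mean everywhere a
full window fits (window-mean tests therefore use the unsmoothed signal).
Trials containing excessive noise are excluded by a rule the source
description leaves unspecified: a trial is dropped when its peak absolute
amplitude exceeds `K = 5` robust SDs (MAD) of that electrode's
trial-peak distribution; `K` is configurable and rejections are counted.
Downsampling to the 200 Hz analysis rate used by decoding and RSA is
plain decimation after smoothing (the moving average is the anti-alias
step; HFA envelopes carry little power near 100 Hz).

## 2. Electrode selection

Responsiveness is tested per category in four stimulus-on windows
(100–300, 300–500, 500–700, 700–900 ms; trials ≥ 900 ms only) against the
200-ms pre-onset mean, with two-tailed paired t tests on unsmoothed
window means. Correction is Bonferroni across the four windows (the
threshold becomes `q < 0.05/4`) and Benjamini–Hochberg FDR across
electrodes. The FDR family is each category × window combination across
electrodes; the family grouping is a documented choice, as "FDR across
electrodes" does not pin it down. Response sign is the sign of the sum of
t statistics over *all* sixteen tests, including non-significant ones —
implemented as stated even though rare mixed electrodes could flip under
a significant-only rule. Category selectivity uses the same windowed
scheme with one-way ANOVAs, and the selectivity time course is
`100·η²(t)` from a pointwise ANOVA on the smoothed traces (matching what
is plotted), with `η² = 0` defined at zero-variance time points.
Attenuation is `100·(P − E)/P` with `P` the 0–900 ms peak and `E` the
800–900 ms mean; it exceeds 100% when late activity dips below baseline.
Region comparisons use `aov` + Tukey–Kramer with pooled-SD Cohen's d.

## 3. State-space trajectories

The neural state at time t is the vector of responses across electrodes.
Because trials are baseline corrected, the multivariate response
magnitude is the L2 norm of that vector; transition speed is the norm of
the one-sample difference rescaled to per-ms; duration tracking is the
norm of the difference between duration-conditioned trajectories,
restricted to the interval where only the longer stimulus is on. The
category selectivity index is the root-mean-square distance of the four
category trajectories from their common mean — a multivariate standard
deviation. Inference uses the shared permutation engine (section 5):
duration labels are shuffled across trials, the same assignment at all
time points. Confidence intervals come from a jackknife that drops one
random trial per patient and condition per iteration and recomputes the
merged-electrode statistic; the 1000 iterations sample the combinatorial
leave-one-out space uniformly under a fixed seed, since the sampling
policy is otherwise unspecified. PCA exists only as a plotting helper;
no inference depends on it.

## 4. Decoding

Pairwise category decoding fits one linear discriminant per time point on
the multi-electrode pattern. Repetitions of the same image are averaged
first so an image can never straddle the train/test split; the larger
class is undersampled to the smaller; folds are stratified. The 5-fold
cross-validation is repeated 5 times with the undersampling redrawn at
each repeat, and results are averaged — averaging first, then testing
significance. The covariance is shrunk toward the scaled identity,
`Σ̂ = (1−λ)Σ + λ·(tr(Σ)/p)·I`, which preserves the trace; `Σ` pools the
class covariances weighted by their trial counts. `λ = "auto"` uses the
Ledoit–Wolf estimator computed on the training folds only — a leakage
guard that cross-validation implies but does not state. When the training
data are exactly zero-variance (noiseless pre-stimulus samples), the
classifier falls back to the mean-difference direction, which yields
constant scores and chance AUC. Performance is AUC computed by the rank
statistic with average-rank tie handling (equivalent to the ROC
integral): 0.5 is chance, 1 perfect separation, and it is invariant to
monotone transforms of the scores. Temporal generalization trains at
every time point and tests at every time point under the same folds, so
the TGM diagonal equals the time-resolved AUC exactly.

A property worth knowing: cross-validated AUC on *null* data is biased
below 0.5 at very small sample sizes (about 0.38 at 12 trials/class,
0.485 at 24, 0.498 at 60), because chance asymmetries between train and
test splits anti-correlate. This is a property of CV itself, not of the
implementation; calibration checks therefore use ≥ 24 trials per class.

## 5. Permutation inference

One engine serves all analyses. A null is built by shuffling the relevant
labels (duration, category, exemplar identity) and recomputing the full
statistic series per permutation, with the same permuted assignment at
every time point to preserve temporal structure. Observed and permuted
series are z-scored by the permutation matrix's column means and SDs
(zero-SD columns give z = 0 rather than NaN). Max-statistic control takes
the maximum z per permutation; significance uses the inclusive p-value
convention `p = (1 + k)/(N_perm + 1) ≤ α`, which floors p at
`1/(N_perm+1)` and — unlike a literal 95th-percentile cut — still controls
the family-wise error at reduced permutation counts (at `N_perm = 1000`
the two are indistinguishable). Cluster-based control thresholds the
statistic in its own units (AUC 0.60; AUC difference 0.10; reliability
z 1.5, or 0.75 for the 100-ms-smoothed single-category analyses; the
analytic ρ threshold for model correlations), sums member values as the
cluster statistic, and compares against the null of per-permutation
maximal cluster masses. TGM clusters use 4-connectivity (shared edge)
over the train × test plane — a documented choice, since "temporal
adjacency including both train and test times" does not specify the
neighborhood. Tests are one-sided except between-region contrasts, where
both signs are clustered. Point-by-point inferences use
Benjamini–Hochberg FDR at q < 0.05.

## 6. Exemplar-level reliability (IR and GR)

Representational dissimilarity matrices are built per repetition and time
point from either correlation dissimilarity `1 − r` or Euclidean
distance; analyses are restricted to images seen at least twice for
≥ 900 ms (the first two repetitions when there are more — the natural
reading when extra repetitions exist).

**Item Reliability** anchors each presentation and Spearman-correlates its
dissimilarity vector to all other images within its own repetition with
its dissimilarity vector to all other images of the other repetition,
averaging over images and repetitions. The null shuffles the stimulus
identity of the *other* repetition only — the anchor is never permuted
(asserted structurally in tests). **Geometry Reliability** builds the
2N × 2N cross-repetition RDM, pairs each within-repetition dissimilarity
set with one between-repetition set (Geometry 1 = within-1 with the
upper between-triangle, Geometry 2 = within-2 with the lower; alternative
pairings give similar results and the same-exemplar cross-repetition
diagonal belongs to neither), averages each pair, and Spearman-correlates
the two unfolded geometries; its null relabels all single exemplars of
repetition 2. GR is deliberately a joint test of reliability *and*
exemplar discriminability: when exemplars are represented
indistinguishably the shuffle null is invariant and GR stays
insignificant even though the geometry is preserved.

Stability matrices generalize both across time: entry (t1, t2) always
correlates structures from *different* repetitions, so temporally
autocorrelated spontaneous activity cannot inflate the off-diagonal; the
diagonal reproduces the reliability time course exactly. Cells are
z-scored against the same shuffle nulls and masked by FDR.

Category structure is removed with Spearman *partial* correlation against
four model RDMs (0 within category, 0.5 between categories sharing a
higher-order group, 1 otherwise): single-category, low-level
({face, watch} vs {object, animal}), semantic ({face, animal} vs
{watch, object}) and face-vs-rest. IR partials out the model's row for
the anchor (diagonal excluded); GR the full unfolded model. Ties take
average ranks throughout. Model–RDM correlation time courses are
cluster-tested with the sum of correlations as the statistic and a
first-level threshold computed analytically as `qnorm(1−α)/√n_pairs` —
0.0391 for the 60-image geometry (1770 pairs) — and recomputed by the same
rule for any other geometry size.

## 7. The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream stage is validated. It emulates
the experimental design — four categories with relative frequencies 0.30
(face), 0.30 (watch), 0.18 (object), 0.10 (animal); durations drawn
uniformly from {300, 900, 1500} ms; epochs −300…1600 ms; repetitions per
image; multiple patients whose electrodes concatenate and whose trials
align by shared unique images, mirroring merged-electrode group
analyses. Regional dynamics follow a coding profile: a quadratic rise to
a transient peak (time-to-peak 60 ms) followed by an exponential decay
(150 ms constant) to a sustained plateau at `sustained_fraction` of the
peak while the stimulus is on, then an exponential return to baseline
after offset. A planted `sustained_fraction` f yields an expected
noiseless attenuation of `100·(1−f)`%; the default visual-region value
0.25 emulates the strong (~four-to-five-fold) post-onset attenuation of
real HFA, and the default frontal value is near zero (transient
ignition-like bursts).

Category and exemplar information enter as per-electrode gains: each
exemplar's pattern is its category tuning column plus an isotropic
perturbation (`exemplar_gain_sd`), which makes IR/GR signal strength
directly controllable. "Dynamic" regions rotate to a second pattern set
mid-trial (200-ms crossfade at `switch_time_ms`); the late patterns are
orthogonalized against the span of the early tuning, the common response
mode, and the realized early category means, and each late exemplar
vector against its early counterpart — so neither category nor exemplar
readouts generalize across the switch, producing diagonal TGMs and
onset-limited reliability. A configurable fraction (default 0.15, i.e.
under 20%) of responsive electrodes is sign-flipped to emulate
negatively responding sites. Noise is additive Gaussian on the HFA
samples plus multiplicative trial-level gain jitter — the simplest model
consistent with the pipeline's assumptions. No quantitative single-
electrode SNR is published for this regime; the default `noise_sd = 0.5`
(in units of normalized HFA, against peak responses of 2–3) was chosen
once to land in the qualitative regime of real recordings — decodable
category structure, attenuated but present late signal — and is
documented rather than fitted. The generator does **not** emulate 1/f
spectra, epileptiform artifacts, eye movements, latency jitter across
trials, or electrode correlations beyond the planted patterns — so
passing tests demonstrate correctness of the statistics under the stated
model, not robustness to every property of clinical data. A raw-trace
mode synthesizes 70–150 Hz carriers amplitude-modulated by the planted
envelope to validate the HFA extraction stage against a known ground
truth.

## 8. Problem sizes and numerical choices

The test suite and the benchmark script run at desk scale, chosen as the
smallest sizes at which each property is statistically decidable: AUC
calibration uses 60 trials/class over 50 electrodes; error-control checks
use 300 null datasets of 20 electrodes × 80 trials with 200 permutations
(the inclusive p-value convention makes 200 sufficient; 100 is not);
reliability analyses in tests subsample the 200 Hz axis (every 4th–20th
sample) and use 200-permutation nulls, against the 1000-permutation
default of `run_pipeline()`. Correlation RDMs are clipped to zero
diagonals; degenerate inputs (zero variance, empty supra-threshold sets,
categories with < 2 trials) return defined values or skip with a message
rather than erroring mid-pipeline. The epoch container is a plain-text
directory (JSON header + 17-significant-digit TSVs) that round-trips
losslessly.

## 9. Known limitations

Electrode localization, raw clinical preprocessing (average referencing
of raw voltage, notch filtering), and saccade detection are out of scope;
the pipeline starts from voltage traces or epochs. The jackknife and
permutation engines assume exchangeability within the shuffled unit
(trials within patient × condition). Real-data headline quantities (mean
attenuation, selectivity decline) require the deposited patient dataset
and are not reproduced here; the measurement functions are exercised on
synthetic data only.
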