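---
title: "Methods: synthetic cohorts, decoding, and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, decoding, and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(eegmvpa)
```

This vignette documents the statistical model behind the package, the
choices made in the synthetic-data generator, and the numerical decisions
that affect results. Code chunks are illustrative and not evaluated at
build time; every number they would produce is recomputed by the test
suite.

## 1. The study design being modelled

The package models a visual category (animacy) EEG experiment comparing
healthy controls (HC) with patients with mild cognitive impairment (MCI):

* 32 stimuli, 16 animal and 16 non-animal, each shown once per run;
* 13 runs, hence 13 repetition trials per stimulus and 416 trials per
  subject;
* 63 scalp electrodes plus one reference (dropped after average
  re-referencing) and 3 EOG channels;
* acquisition at 1200 Hz, epochs over the half-open window
  [−100, 800) ms (1080 samples), later resampled to 1000 Hz
  (900 samples).

`synthetic_design()` encodes these constants as defaults; every one of
them can be reduced for quick experiments, and the test suite does so
extensively.

## 2. The generative model

`generate_subject()` draws trial data

```
x(trial, channel, t) = a_subj * k(t − j_subj) * [ p_class(channel)
                        + s * q_stim(channel) ] + noise
```

* `k(t)` is a raised-cosine kernel rising from the class onset latency to
  the peak latency and decaying symmetrically. It is smooth, compactly
  supported and has an unambiguous peak — the three properties the
  latency analyses rely on.
* `p_class` are unit-norm spatial patterns for the two classes,
  constructed as `(m ± d)/√2` from orthonormal vectors `m` (class mean)
  and `d` (class contrast). Both are orthogonal to the all-ones vector so
  that average re-referencing leaves the signal untouched.
* `q_stim` are per-stimulus unit-norm patterns shared by both groups,
  scaled by `stimulus_amplitude` (default 0.5). They make stimuli within
  a class discriminable, which is what gives pairwise-decoding RDMs
  non-trivial structure.
* `j_subj` and `a_subj` are per-subject latency and amplitude jitter
  (defaults: SD 12 ms and 0.1), giving realistic between-subject
  variability; noise is i.i.d. Gaussian by default with an optional
  stationary AR(1) variant (`ar1`), scaled so the marginal SD stays
  `noise_sd`.

Group effects are controlled by `group_effects()`:

* **Latency delay.** Default onsets 110 (HC) vs 150 ms (MCI) and peaks
  250 vs 290 ms — a 40 ms group delay.
* **Amplitude deficit.** Default evoked amplitudes 1 (HC) vs 0.85 (MCI).
* **Pattern divergence.** `pattern_divergence` rotates the MCI class
  contrast `d` by `divergence × 90°` towards a third orthonormal
  direction. The rotation is an isometry: within-group decodability is
  unchanged, only the *spatial organisation* differs between groups.
* **Mean matching.** `mean_matched = TRUE` forces MCI latencies and
  amplitude to equal HC's, so the mean evoked response (and hence every
  region-level ERP) is identical between groups by construction, while
  pattern divergence still separates them multivariately. This is the
  regime in which multivariate measures dissociate groups that univariate
  ERPs cannot.

A consequence worth knowing: because the rotation is an isometry, group
differences in pairwise-decoding RDMs appear only in cells that are not
saturated at accuracy 1. They are therefore largest at latencies of
intermediate decodability, not at the accuracy peak.

`generate_continuous_session()` produces the same design as a continuous
recording (scalp + reference + EOG channels, stimulus events every 2 s)
with raised-cosine blink artifacts projected onto the EOG channels and,
attenuated, onto the frontal scalp rows — the input expected by the
preprocessing chain and the BrainVision round-trip.

## 3. Preprocessing

`preprocess_pipeline()` applies six stages in a fixed order:

1. average re-reference over the scalp channels and removal of the
   reference channel;
2. FastICA decomposition of the scalp channels and subtraction of the
   single component most correlated with any EOG channel;
3. epoching over [−100, 800) ms (half-open: the sample at t = 0 belongs
   to the post-stimulus side);
4. per-trial, per-channel z-normalisation by the pre-stimulus baseline;
5. 4th-order Butterworth 50 Hz low-pass, applied forward and backward
   for zero phase;
6. resampling to 1000 Hz.

Normalisation deliberately precedes filtering; the pipeline reproduces
that published order rather than the more common filter-first ordering.

Numerical decisions:

* **ICA rank.** After average re-referencing the scalp data have rank
  n−1, so at most n−1 components are requested (at most 20).
  If the decomposition fails outright the data are returned unchanged
  with a warning rather than silently half-cleaned.
* **Filter edges.** Forward–backward IIR filtering from zero initial
  state leaves edge transients; the filter is therefore applied to an
  odd-reflection padded copy of each epoch and the padding discarded.
* **Resampling.** 1200 → 1000 Hz is a non-integer rate change. Polyphase
  resampling as implemented in the available signal-processing library
  showed errors around 0.3 (signal units) on band-limited test tones, so
  the package instead interpolates with cubic splines onto the target
  grid (errors around 1e−5 at 40 Hz). This is accurate precisely because
  resampling runs *after* the 50 Hz low-pass, which leaves the signal far
  below the new Nyquist frequency; `resample_epochs()` refuses to
  upsample.

## 4. Time-resolved decoding

`decode_timecourse()` implements bin-sub-averaged animacy decoding:

* stimuli of each class are randomly partitioned into bins of 2, 3 or 4
  stimuli (a random remainder is dropped when the class size is not
  divisible); all repetition trials of a bin are averaged into one
  exemplar, raising SNR;
* at each time point, the features are the scalp-channel values of the
  exemplars at that single sample;
* accuracy is leave-one-bin-out cross-validation of a linear SVM
  (cost C = 1, no feature scaling). Binning at the *stimulus* level
  prevents repetition trials of one stimulus from appearing on both
  sides of a fold;
* the procedure repeats over random bin assignments (10,000 by default;
  every analysis here reduces this) and accuracies are averaged. In the
  default "mixed" mode each repetition draws its bin size uniformly from
  the candidate sizes; sizes that would leave a class with fewer than two
  bins are rejected.

Peak latency is the post-stimulus accuracy maximum (earliest sample on
ties). `compare_peak_latency()` tests the MCI-minus-HC difference of
group median peak latencies with a participant-subsampling bootstrap.

## 5. Representational geometry

`compute_rdm()` builds a 32 × 32 representational dissimilarity matrix
whose cell (i, j) is the stratified leave-one-trial-out CV accuracy of a
linear SVM discriminating stimuli i and j — chance 0.5 for indistinguishable
stimuli, 1 for perfectly separated ones. `rdm_distance_timecourse()`
summarises the group difference as the Euclidean distance between the
upper triangles of the HC-mean and MCI-mean RDMs, locates its maximum
over time, and tests it by permuting subjects between groups.

For display the distance is monotonically rescaled to [0, 1] with a
logarithmic map anchored at (minimum, pre-stimulus baseline, maximum).
The anchored log family is concave, so baseline images at or below the
linear map are unattainable; `scale_distance()` then falls back to the
linear map with a warning. The raw distance is authoritative — the
scaled value never enters a test. `mds_embed()` (classical scaling
followed by Sammon refinement) visualises single RDMs.

## 6. Group classification and inference

`classify_groups_timepoint()` treats each subject's flattened
channels × stimuli activation pattern at one latency as one observation
and reports leave-one-subject-out CV accuracy of a linear SVM
(stratified: each fold holds out one subject per group, keeping training
folds balanced; residual imbalance from unequal group sizes is absorbed
by inverse-class-frequency penalty weights), with a
participant-subsampling bootstrap (draws of 80% of each group without
replacement) supplying the p-value against chance.
`classify_groups_from_rdms()` does the same with upper-triangle RDM
vectors as features.

All resampling p-values use `(count + 1) / (n + 1)`, so the smallest
attainable p with 10,000 resamples is 1/10001 ≈ 0.0001. Exceptions are
permutation tests small enough to enumerate exhaustively, which use the
exact `count / N` including the observed relabeling. Rank-sum and
sign-rank tests wrap the standard Wilcoxon implementations; families of
tests over time points, RDM cells, or regions are corrected with
Benjamini–Hochberg FDR.

## 7. Problem sizes and limitations

The defaults reproduce the full design (416 trials, 63 channels,
10,000 bin randomisations); at that scale a single full-resolution
decoding time course is hours of CPU. All package tests and the
`run_study()` report therefore reduce repetitions, subjects, channels
and sampling rate — the implementation is identical, only the sizes
differ.

Known limitations:

* the generator's noise is spatially white; real EEG noise is spatially
  correlated, so absolute accuracies are not calibrated to empirical
  effect sizes;
* blink artifacts are the only modelled artifact class;
* only the BrainVision subset the package itself writes (multiplexed
  IEEE float 32) is importable; other continuous formats are rejected
  with an error rather than guessed at;
* peak-latency recovery is reliable at high evoked SNR; with weak
  signals the post-stimulus argmax is noise-dominated and group
  comparisons lose power — the test suite demonstrates recovery in the
  high-SNR regime and the absence of false positives under a null shift.

## 8. A minimal end-to-end run

```{r study, eval = FALSE}
study <- run_study(n_hc = 6, n_mci = 6, n_repetitions = 50,
                   n_boot = 1000, seed = 1)
write_report(study, "report")
```

This simulates a reduced cohort with the default group effects (40 ms
delay, amplitude deficit), decodes every subject, tests the latency
delay, computes RDM series and the group RDM distance, classifies HC vs
MCI at the decoding peak, and writes the tables `accuracy.tsv`,
`peaks.tsv`, `latency_test.tsv`, `rdm_distance.tsv` and `summary.tsv`.
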