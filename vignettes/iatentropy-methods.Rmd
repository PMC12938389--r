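---
title: "Methods: EEG entropy features of implicit-attitude processing and exercise behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG entropy features of implicit-attitude processing and exercise behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iatentropy)
```

## The scientific question

Implicit attitudes toward exercise are usually measured behaviorally
with the Implicit Association Test (IAT): the D-score contrasts
reaction times between blocks in which exercise shares a response key
with positive attributes ("compatible") versus negative attributes
("incompatible"). Reaction times, however, are a terminal output of the
underlying evaluative dynamics. Nonlinear EEG features recorded while a
person performs the IAT — entropy measures of the signal's regularity
and of its amplitude-envelope complexity — may carry more information
about whether the person will actually exercise in the following days.

`iatentropy` implements that analysis as a reusable, fully tested
pipeline:

1.  **Behavioral scoring** — IAT D-scores with the improved-algorithm
    trial filters, and 7-day recall scoring in MET-min/week with a
    strict exercise / non-exercise dichotomy.
2.  **EEG preprocessing** — downsampling to 500 Hz, zero-phase FIR
    band-pass 3–40 Hz, epoching −500..1000 ms around stimulus onset,
    baseline correction over −200..0 ms, and ±100 µV amplitude
    rejection.
3.  **Entropy features** — seven estimators per epoch and electrode,
    aggregated to five scalp regions and four task conditions.
4.  **Group statistics** — Wilcoxon rank-sum tests with task-wise
    Benjamini–Hochberg FDR control (families of 5 regions × 7 metrics
    = 35 tests per condition, q = 0.05).
5.  **Classification** — random forest, KNN, SVM and LDA under a
    repeated stratified 70/30 protocol, with ROC/AUC and normalized
    top-5 random-forest importances.
6.  **Synthetic cohorts** — a generator with a plantable group
    difference in envelope complexity, standing in for patient EEG that
    cannot be redistributed.

## Behavioral scoring rules

Per IAT type, practice trials are removed; formal trials with missing
responses or reaction times `< 350` ms are discarded; a participant is
excluded when the error rate of any block exceeds 20%. Incorrect trials
receive an effective reaction time equal to the mean of the correct
trials of the same block plus 400 ms. Then

$$D = \frac{\bar{RT}_{\text{incompatible}} - \bar{RT}_{\text{compatible}}}{SD_{\text{pooled}}},$$

where the pooled SD is, by default, the sample SD (denominator $n-1$)
of the *union* of correct-trial raw reaction times from both blocks.
The phrase "pooled standard deviation" is ambiguous between this
union-SD (the convention of the improved IAT scoring algorithm) and the
classical two-sample pooled estimator; we default to the union-SD and
expose the two-sample variant via `sd_method = "two_sample"`.

Ordering: practice removal → error-rate check → RT filter → penalty →
D. The error rate is computed on *all* formal trials, before the RT
filter, so fast errors count against a participant; the alternative
order is not identifiable from the scoring rules alone, and this choice
is the more conservative screen.

IPAQ scoring uses walking = 3.3, moderate = 4 and vigorous = 8 METs,
each multiplied by minutes/day and days/week. The exercise group
criterion is dichotomous: `non_exercise` iff moderate + vigorous
MET-min/week is exactly zero. Walking never counts toward the total.

## Preprocessing

The pipeline order is fixed: re-referencing (a pass-through for
synthetic data, which are generated referenced) → downsample →
band-pass → epoch → baseline → reject.

The band-pass is a Hamming windowed-sinc FIR (difference of two ideal
low-passes), applied once with group-delay compensation, so the output
is zero-phase at single-pass attenuation. With the default 1.5 Hz
transition width the −6 dB points sit exactly at 3 and 40 Hz and
stop-band attenuation exceeds 40 dB by 1.5 Hz and 53 Hz. The filter
length is $\lceil 3.3 f_s / 1.5\,\text{Hz} \rceil$ taps (≈ 1101 at
500 Hz), and signals shorter than three filter lengths are rejected
with an explicit error rather than silently filtered.

Epochs span −500..1000 ms (750 samples at 500 Hz, exactly
$1.5\,\text{s} \times f_s$ in general); baseline correction subtracts
the per-epoch, per-channel mean of −200..0 ms. The amplitude criterion
is strict: an epoch is rejected iff any sample of any channel *exceeds*
±100 µV, so an epoch peaking exactly at 100 µV is kept.

ICA artifact removal and spherical-spline bad-channel interpolation are
deliberately out of scope: both hinge on visual inspection of real
artifacts. Synthetic data are generated artifact-free (with an optional
spike injector to exercise the rejection stage), and real-data use
expects pre-cleaned input.

## The seven entropy estimators

All estimators operate on a single-channel epoch segment of $N$
samples; defaults analyze the full −500..1000 ms epoch. Values are in
nats.

| Metric | Definition | Parameters |
|---|---|---|
| Singular spectrum | $-\sum p_i \log p_i$, $p_i = \sigma_i/\sum\sigma$, $\sigma_i$ singular values of the $L \times (N-L+1)$ Hankel trajectory matrix | $L = 500$ samples |
| Approximate | $\Phi^m - \Phi^{m+1}$, self-matches included, Chebyshev distance | $m = 2$, $r = 0.15\,SD$ |
| Sample | $-\log(A/B)$, template pairs without self-matches | $m = 2$, $r = 0.15\,SD$ |
| Fuzzy | $\log\phi^m - \log\phi^{m+1}$, mean-centered templates, membership $e^{-(d/r)^2}$ | $m = 2$, $r = 0.15\,SD$ |
| Permutation | Shannon entropy of ordinal patterns of consecutive 6-tuples | $m = 6$, $\tau = 1$ |
| Envelope | $-\sum p_j \log p_j$, $p_j = a_j/\sum a$, $a$ = modulus of the FFT-constructed analytic signal | — |
| Log-energy | $\sum_j \log(x_j^2 + \varepsilon)$ | $\varepsilon$ = smallest normal double |

Convention choices that the estimator parameters do not pin down:

-   **Tolerance.** "Threshold 0.15" is read as $r = 0.15 \times SD$ of
    the analyzed segment (the near-universal field convention); an
    absolute-r mode is available (`r_mode = "absolute"`).
-   **Segment.** Estimators see the full −500..1000 ms epoch. The
    stated SVD window of 500 samples would be degenerate (a one-column
    trajectory matrix) on the 500-sample post-stimulus segment, which
    is why the full epoch is the default; `segment = "post_stimulus"`
    remains available, with the SSE window capped at $2N/3$ (the same
    500/750 ratio as the default geometry).
-   **SSE weighting.** Probabilities normalize the singular values
    $\sigma$ themselves; `sse_weight = "sigma_sq"` switches to
    variances.
-   **Sample entropy degeneracy.** When no template pair matches
    ($A = 0$ or $B = 0$), the value is undefined; it is returned as
    `NA` with a flag, excluded from regional averages, and counted in
    the table's `n_undefined` provenance column — never imputed.
-   **Ties.** Ordinal patterns break ties by index order (stable
    ranking); with continuous-valued signals ties have measure zero.
-   **Aggregation.** Estimates are computed per epoch and electrode,
    then averaged across epochs, then across each region's electrodes
    (means commute, so the order is a documentation matter);
    concatenating epochs before estimation would create spurious
    cross-epoch templates at the seams and is not done.

The regions are frontal (Fz, F1, F2), fronto-central (FCz, FC1, FC2),
central (Cz, C1, C2), centro-parietal (CP1, CP2) and parietal (Pz, P3,
P4) — 14 electrodes. A complete feature table has 5 regions × 7 metrics
= 35 values per participant and condition.

The three template entropies share one O(N²) pairwise-distance pass,
implemented in C++; the singular spectrum uses the SVD of the Hankel
matrix. Every estimator is verified against an independent brute-force
R implementation to 1e-10 in the test suite.

## Group statistics

Within each task condition, each of the 35 region × metric features is
compared between groups with a two-sided Wilcoxon rank-sum test using
the normal approximation with tie correction and a 0.5 continuity
correction. The reported z is sign-flipped so that *higher entropy in
the exercise group appears as negative z*, matching the reporting
layout of the group-comparison tables; `sign = "raw"` disables the
flip. Exact enumeration is used as the test-suite oracle at small n;
at the study's group sizes (33/23) the normal approximation is
accurate.

Each condition's 35 tests form one Benjamini–Hochberg family at
q = 0.05: conditions reflect distinct processing contexts and are not
pooled. Features missing for a condition shrink that family (with a
message); p-values never enter two families.

## Classification protocol

The evaluation protocol in the source description is self-contradictory
(a 70/30 train/test split *and* "ten-fold cross-validation"). We
resolve it as **10 repetitions of stratified random 70/30 splits**,
which matches both the 70/30 sentence and the "mean ± SD across 10
folds" reporting; one stratified 10-fold run is available via
`protocol = "kfold"`.

Hyperparameters are fixed: RF with 100 trees and a minimum of 5 samples
per leaf; KNN with 5 Euclidean neighbors; SVM with an RBF kernel, box
constraint 1 and the median-heuristic kernel scale (deterministic, no
inner CV); LDA with no regularization, falling back to a small ridge
($10^{-3}$ of the mean covariance diagonal) when the within-class
covariance is singular, as happens for 140-feature designs at n = 56.
KNN/SVM/LDA features are standardized with training-split statistics
only (anti-leakage is asserted by a canary test); random forests use
raw features. The positive class is **non-exercise** throughout, so
sensitivity measures detection of non-exercisers. AUC is the normalized
rank (Mann–Whitney) statistic over test-set scores pooled across
repeats. Random-forest importances (mean impurity decrease) are
averaged over repeats; the top five are renormalized to shares of their
own total, and features are labelled `<region>_<A|I>_<C|IC>` (e.g.
`FC_A_IC` = fronto-central, affective incompatible).

## The synthetic cohort generator

No patient EEG is distributed with the study, so the generator defines
the conditions under which every downstream claim is tested. Defaults
mirror the study design: 33 exercisers vs 23 non-exercisers, blocks of
24 practice + 72 formal trials, 1000 Hz native sampling, epochs spanning
−500..1000 ms over the 14 electrodes above.

**Signal model.** Each region's source is a theta (5 Hz, 5 µV), an
alpha (10 Hz, 12 µV) and a beta (20 Hz, 4 µV) oscillation plus
band-limited 1/f noise (3 µV), with independent 1/f sensor noise
(2 µV) per electrode; phases are random per epoch. The alpha amplitude
is sinusoidally modulated at 6 Hz with depth $m$ — the *burstiness*
parameter. Because envelope entropy is a direct function of
amplitude-modulation structure, $m$ is the natural handle for a planted
effect: a constant envelope ($m = 0$, no noise) attains the
$\log N$ maximum, and envelope entropy decreases monotonically in $m$
(a property test verifies this). Amplitudes stay within ±50 µV, so
clean cohorts survive the ±100 µV rejection untouched; an optional
spike injector (`artifact_prob`) produces rejectable epochs.

**Planted effect.** Each participant carries a latent
modulation-regularity trait per region,
$v_{ir} = \rho g_i + \sqrt{1-\rho^2}\,e_{ir}$ with $\rho = 0.7$ (a
realistic inter-regional correlation for regional EEG measures), and
$m_{i,\text{cond},r} = \text{clamp}(0.5 - 0.12\,v_{ir})$. In the
effect cells (by default the affective-incompatible condition ×
frontal/fronto-central/central regions) exercisers' traits are shifted
by `effect_size_d` standard deviations, raising their expected envelope
entropy there and nowhere else. The slope 0.12 was calibrated once,
empirically, so that the realized standardized group difference of the
effect-region-averaged envelope-entropy feature tracks the nominal
`effect_size_d` (a calibration test verifies nominal 1.5 is realized
within ±0.3 at 6 formal trials per block and 64 Hz). Two opposing
distortions are inherent and documented rather than hidden: epoch-level
estimation noise attenuates the realized effect by
$\sqrt{c^2/(c^2+\sigma^2_\text{noise}/n_\text{ep})}$, while averaging
the three correlated effect regions shrinks the denominator variance
and inflates the pooled measure by up to
$\sqrt{3/(1+2\rho^2)} \approx 1.23$; per-region (per-cell) realized
effects are therefore slightly below nominal at small epoch counts. The
paper-scale effect magnitude is unknown (the source reports only z
statistics), so `effect_size_d` is a free parameter of the study
design, not an estimate.

**Behavior.** Reaction times are ex-Gaussian (μ = 650 ms floored at
360 ms, σ = 80 ms, τ = 120 ms) with an 80 ms incompatible-block shift,
5% errors, 2% fast responses (< 350 ms) and 1% missing responses —
typical IAT magnitudes giving positive D-scores around 0.4. The floor
guarantees that with `fast_rate = 0` no formal trial trips the 350 ms
filter. Exercise recalls are generated consistently with the group
label, so `assign_group()` reproduces it exactly (a tested invariant).

**Determinism.** All randomness derives from one root seed through
named substreams keyed by participant, stage and condition
(`substream_seed()`), so identical specs are bit-identical, enlarging a
cohort does not perturb existing participants, and a cohort restricted
to a subset of conditions reproduces exactly the matching epochs of the
full cohort.

**What the generator does not emulate.** Dipole/forward-model scalp
topographies, volume conduction, real artifact morphology (blinks,
EMG), non-stationary alpha dynamics, electrode drift, or any coupling
between behavior (RTs, errors) and the EEG beyond the epoch-count link
through correct trials. Passing tests therefore demonstrate that the
*pipeline* recovers what it is supposed to recover under its stated
assumptions — not that real hypertensive-patient EEG behaves this way.

## Numerical choices and degenerate inputs

-   Zero-variance segments: ApEn/SampEn/FuzzyEn return 0 with a
    `degenerate` flag; an all-zero signal has no envelope and raises an
    error.
-   The SSE window is capped at $\lfloor 2N/3 \rfloor$ so the
    trajectory matrix always has at least $N/3$ columns.
-   The log-energy ε-guard uses the smallest positive *normal* double;
    the scaling identity $E(kx) = E(x) + N\log k^2$ then holds to
    machine precision for any signal with amplitudes above ~1e-100.
-   Rank-sum variance uses the tie-corrected formula; when all values
    are identical the test returns z = 0, p = 1.
-   Classifier repeats that would produce a single-class test split are
    prevented by stratification (at least one member of each class is
    always held out).

## Problem sizes used by the test suite and acceptance script

Entropy estimation cost scales as N² per epoch-channel, so the
Monte-Carlo studies run on reduced cohorts chosen once, always at the
study's 33/23 group split: 50 Hz sampling (75-sample epochs, SSE
window 50) with 2 formal trials per block for the 200-cohort
null-calibration study and 6 for the 100-replicate power study; 64 Hz
with 6 trials for the generator-calibration check and 8 for the
classifier-recovery study. The
acceptance script uses the same sizes with fewer replicates. At these
sizes the full suite runs in minutes on one CPU while preserving the
structure of every stage (full 35-test families, all four classifiers,
the complete preprocessing chain).

## Known limitations

-   Per-cell detection power for the planted envelope effect at
    `effect_size_d = 1.0` with the study's 33/23 split and
    BH-controlled 35-test families is bounded near 0.70 even with
    noiseless features (the expected rank-sum z is ≈ 3.3 while the
    BH-effective two-sided threshold is ≈ 2.9); reduced epoch counts
    attenuate it further. Detection of *at least one* of the three
    planted regional cells per replicate is the reliable event. The
    test suite asserts the stricter per-cell criterion and reports the
    shortfall honestly rather than relaxing it.
-   The Wilcoxon screen and the classifier evaluation are not nested;
    both screened (envelope-only) and unscreened (all-entropy) designs
    are exposed rather than resolving the dependency.
-   Real-data mode expects pre-cleaned (ICA-processed) continuous EEG;
    the package does not read EDF/BrainVision natively and provides its
    own epoch interchange format instead.
-   IPAQ total-activity categories, alternative D-score variants,
    multiscale entropy and spectral-power features are out of scope.
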