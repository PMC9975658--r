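# speechsync

Speech comprehension at fast syllabic rates varies widely between
listeners, and part of that variability appears to track properties of the
*motor* system: how strongly a listener's speech production spontaneously
synchronizes to heard syllable trains, and how fast they spontaneously
articulate. `speechsync` is an R package for researchers in auditory and
speech neuroscience who want to quantify these individual differences from
behavioural data and relate them to trial-level comprehension with a
mixed-model analysis. Because real speech-production recordings typically
cannot be shared, the package also ships a synthetic-data generator with
known ground truth for every measure, so the entire pipeline is testable
and demonstrable without any restricted data.

## What it computes

**Auditory-motor synchronization.** From a syllable-train stimulus and a
(whispered) production recording, the package extracts amplitude envelopes
— a gammatone/ERB cochlear envelope (180–7246 Hz) for the stimulus, the
Hilbert envelope for the production — downsamples them to 100 Hz,
band-passes 3.5–5.5 Hz with a zero-phase Butterworth response, takes
instantaneous phases θ₁, θ₂, and computes the phase-locking value

    PLV = (1/T) | Σₜ exp{i(θ₁(t) − θ₂(t))} |

in 5 s windows with 2 s overlap, averaged to trial- and participant-level
means. k-means (k = 2) on the participant PLVs labels each participant a
HIGH or LOW synchronizer (higher cluster centre = HIGH).

**Spontaneous speech motor production rate.** Syllable nuclei are detected
as intensity-contour peaks (25 ms frames, 10 ms hop; peaks above a
median-relative threshold with a minimum 2 dB dip between nuclei), silent
pauses ≥ 0.3 s are excluded, and the articulation rate is nuclei per
second of voiced time.

**Preferred auditory rate.** Two-interval forced-choice preferences over
syllabic rates (3.00–8.50 syl/s) are aggregated into a preferred-frequency
distribution (catch-trial failures excluded at < 75% correct) and fitted
with a Gaussian; the peak is the preferred rate and FWHM = 2√(2 ln 2)·σ
indexes preference specificity.

**Linguistic predictability.** Sentence perplexity
PPL = (Π pᵢ)^(−1/N) from per-word probabilities supplied by any provider;
a deterministic add-k n-gram provider is included.

**Comprehension scoring and inference.** Intelligibility scoring (multiset
word matching), word-order judgement scoring, and a per-item word-order
index from control data; then a binomial-logit mixed model of trial-level
accuracy with crossed participant/item random intercepts and a
by-participant syllabic-rate slope, reporting per-SD odds ratios, Wald
tests, likelihood-ratio model comparison, Benjamini–Hochberg FDR control,
and VIF collinearity diagnostics.

## Worked example

The end-to-end demonstration generates a full synthetic cohort (82
participants, 240 items) and runs every stage:

```r
library(speechsync)
res <- run_synthetic_cohort(run_config(), seed = 1)
print(res)
#> <cohort_results: 82 participants, seed 1>
#>   PLV cluster centres: HIGH 0.750 / LOW 0.371 (label agreement 97.6%)
#>   motor rate: M = 4.30 syl/s; preferred rate: M = 5.50 syl/s
#>   GLMM: syllabic-rate OR 0.67; LRT for linguistic terms chi2 = 247.0 (p = 1.8e-50)
```

The cohort's PLV distribution is bimodal with cluster centres near 0.75
and 0.37, and k-means recovers 97.6% of the generating HIGH/LOW labels.
The mean articulation rate (4.30 syl/s) and preferred auditory rate
(5.50 syl/s) match the generator's cohort settings. In the mixed model,
the syllabic-rate odds ratio of 0.67 means the odds of a correct
word-order judgement fall by about a third per SD of rate; the
likelihood-ratio test shows the linguistic covariates (perplexity,
target-word probabilities, length, target distance, compression) jointly
improve fit. Accuracy declines across rate conditions:

```r
res$rate_accuracy
#> # A tibble: 6 × 5
#>    rate     n accuracy ci_lower ci_upper
#>   <dbl> <int>    <dbl>    <dbl>    <dbl>
#> 1   5    3280    0.895    0.884    0.905
#> 2  10.7  3280    0.865    0.853    0.877
#> 3  12.5  3280    0.789    0.775    0.803
#> 4  13.6  3280    0.813    0.799    0.826
#> 5  14.4  3280    0.758    0.743    0.773
#> 6  15    3280    0.782    0.768    0.796
```

`tidy(res$fit)` returns the full coefficient table (estimates, SEs, odds
ratios, p-values); `res$coefficients` adds FDR-adjusted p-values and
`res$recovery` compares every estimate against the generating truth.
`autoplot()` methods exist for classifications, PLV results, nuclei
detections, preference fits and model fits.

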