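---
title: "Methods: auditory-motor synchronization and speech comprehension analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditory-motor synchronization and speech comprehension analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(speechsync)
```

This vignette documents the models and procedures the package implements,
the assumptions and defaults behind them, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
careful user should know about.

## The measurement model

The package quantifies four participant-level characteristics and relates
them to trial-level speech comprehension.

### Auditory-motor synchronization (PLV)

Synchronization between heard and produced speech is measured on amplitude
envelopes. The stimulus (a syllable train) is converted to a *cochlear*
envelope: the waveform passes through a bank of 4th-order gammatone
filters whose centre frequencies are spaced uniformly on the ERB-rate
scale across 180–7246 Hz, each channel is Hilbert-rectified, channel
envelopes are aligned for filter delay and averaged. The production
recording (whispering has little harmonic structure, so a single broadband
envelope suffices) uses the absolute value of the analytic signal
directly. Both envelopes are downsampled to 100 Hz, band-pass filtered to
3.5–5.5 Hz — bracketing the 4.3–4.7 syl/s stimulus rates — and their
instantaneous phases $\theta_1, \theta_2$ extracted by the Hilbert
transform. The phase-locking value

$$\mathrm{PLV} = \frac{1}{T}\left|\sum_{t=1}^{T}
  e^{i(\theta_1(t)-\theta_2(t))}\right|$$

is computed in 5 s windows with 2 s overlap; window PLVs are averaged
within trial and trial PLVs across runs (the window-mean-then-run-mean
order is the default; pooling all windows is available by passing the
concatenated series). k-means with $k=2$ (50 restarts, fixed seed, lowest
within-cluster sum of squares kept) splits the participant PLV
distribution; the cluster with the larger centre is labelled HIGH.
Bimodality of the PLV distribution is *assumed*, not re-tested — the
classifier always returns two groups. A mean-silhouette diagnostic is
reported so that degenerate cohorts are visible; on clearly unimodal data
the split is arbitrary and the silhouette will say so.

Key defaults: 30 gammatone channels (the channel count and combination
rule of cochlear-envelope analyses vary between toolboxes and are rarely
reported; 30 ERB-spaced channels with an across-channel mean is a
reasonable, declared choice, not a claim about any particular toolbox);
band 3.5–5.5 Hz; window 5 s / overlap 2 s; 1 s edge trim (below).

### Spontaneous speech motor production rate

The articulation rate is syllable nuclei per second of voiced time.
Nuclei are detected on an intensity contour (25 ms frames, 10 ms hop, dB
scale): candidate peaks must exceed both the median frame intensity plus
`threshold_db` (2 dB) and a voicing floor 25 dB below the contour maximum,
and successive nuclei must be separated by an intensity dip of at least
`dip_db` (2 dB) — the dip criterion prevents amplitude ripple within one
syllable from being counted twice. Runs of sub-floor frames of at least
0.3 s are pauses and are excluded from the voiced duration. These
thresholds follow the conventions of published intensity-based
nuclei-detection scripts; the exact values used by any given lab are
usually unreported, so all four are exposed as arguments. A periodicity
(voicing) check is deliberately absent by default: the whispered and
burst-noise signals this package targets are unvoiced.

Per-participant rates are unweighted means over fixed-length trials;
trials with no detectable nuclei are dropped and participants without any
valid trial flagged rather than silently imputed.

### Preferred auditory rate

2IFC preference trials over a 7-point rate grid (3.00–8.50 syl/s,
self-pairs included) are aggregated — after excluding participants below
75% catch-trial accuracy (performance exactly at 75% is retained) — into
counts of how often each rate was preferred. A Gaussian
$a\,e^{-(r-\mu)^2/2\sigma^2} + d$ is fitted by Levenberg–Marquardt least
squares; $\mu$ is the preferred rate and $\mathrm{FWHM} =
2\sqrt{2\ln 2}\,\sigma$ the specificity.

The additive baseline $d$ deserves a note. In any fair pairwise
forced-choice design every rate wins some trials — a self-pair guarantees
its rate one count regardless of preference — so the expected count
profile is a preference-shaped bump *on a floor*, never a pure Gaussian.
Fitting without an offset therefore systematically overestimates the
width (on noise-free rank-ordered choices the distortion is roughly a
factor of 1.5 in FWHM). With the baseline term the generator's peak and
FWHM are recovered essentially without bias. `baseline = FALSE` restores
the pure-Gaussian fit for comparison with analyses that used it. The fit
is performed on raw counts; because peak and FWHM are invariant to
scaling the counts, fitting proportions instead would change nothing.

### Linguistic predictability

Sentence predictability is summarized as perplexity. The phrase "inverse
of the mean probability of a sentence weighted by sentence length" admits
two readings; the package defaults to the field-standard geometric-mean
definition $\mathrm{PPL} = (\prod_i p_i)^{-1/N}$, computed in log space
(1000 tokens at $p=10^{-6}$ is exact, no underflow), and offers the
literal arithmetic-mean reading ($1/\bar p$) behind
`formula = "arithmetic"`. Word probabilities come from any provider
function; the built-in add-k n-gram provider (closed vocabulary plus an
OOV symbol, conditional probabilities summing to one per context) is a
deterministic stand-in for neural language models, adequate for testing
the perplexity pipeline but not a model of human expectation. Bigram
sentences are conditioned on a start-of-sentence context; no end token is
scored.

### Comprehension scoring

Intelligibility is the percentage of reference words present in the
response under case-insensitive, punctuation-free *multiset* matching
(`min(count_ref, count_resp)` per word type). Order-free matching is the
common intelligibility convention and makes the score deterministic;
whether a word repeated more often in the response than in the reference
should earn extra credit is genuinely ambiguous in manual scoring — the
multiset rule (it does not) is the declared convention here. Word-order
trials score 1 when the word chosen as "heard first" is the true first
target. The control experiment's word-order index is simply the per-item
percentage of control participants guessing the order correctly.

### Trial-level inference

Comprehension is modelled with a binomial-logit mixed model: fixed
effects for the variables of interest plus nuisance covariates, crossed
random intercepts for participant and item, and a by-participant random
slope for syllabic rate. The mixed-model machinery is delegated to
**lme4** — the model itself is entirely standard; the package owns the
design assembly, z-scoring, and all reporting (odds ratios as
`exp(coef)`, Wald z p-values, AIC, likelihood-ratio tests, BH-FDR via
`p.adjust`, VIF from the inverse correlation matrix). Continuous
predictors are z-scored over the analyzed trials *after* exclusions (the
alternative order is obtainable by scoring before excluding), so each
odds ratio is per SD. The slope-intercept correlation is not estimated by
default (`||` parameterization): it is weakly identified at typical
scales and its omission matches the generator. If the full
random-effects model fails to converge the fit falls back to random
intercepts only, with a warning — mirroring standard practice. Laplace
approximation (`nAGQ = 1`) is the default; `nAGQ = 0` (penalized
weighted least squares on the spherical random effects) is offered for
large simulation studies, where it is about five times faster and its
fixed-effect estimates and standard errors agree with Laplace to three
decimals at the 82 × 240 scale.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known
truth: it defines the study conditions under which the package is
validated.

* **Stimulus trains** step through 4.3–4.7 syl/s in 0.1 syl/s blocks of
  60 syllables (≈ 66.7 s). Because a train can equally be specified by
  total duration (e.g. an 80 s run), both sizing modes exist; neither is
  privileged.
* **Coupled phases.** Production phase = stimulus phase + lag + ε(t).
  The noise ε must do two jobs at once: have an exactly von Mises
  marginal, so that the analytical identity
  $E[\mathrm{PLV}] = I_1(\kappa)/I_0(\kappa)$ anchors every calibration
  test, and be slow, so θ₂ remains a plausible band-limited phase.
  Low-pass filtering i.i.d. von Mises samples would destroy the first
  property (smoothing shrinks circular dispersion, inflating the
  realized PLV above the Bessel ratio). The generator instead maps a
  unit-variance AR(1) process through the von Mises quantile function
  (a Gaussian copula): the marginal is exact at every sample and the
  correlation time (default 0.1 s) sets the smoothness. The remaining
  finite-length bias of the windowed estimator is small but real —
  about +0.01 at PLV ≈ 0.36 for 5 s windows — and is absorbed into the
  cohort calibration below.
* **Cohorts.** Group concentrations default to κ_high = 2.15 and
  κ_low = 0.72, chosen once so that *realized* windowed participant
  PLVs land near the observed group descriptives (0.73 / 0.36, spread
  0.09); participant-level spread comes from drawing each participant's
  target PLV around the group mean before inverting the Bessel ratio.
* **Burst speech.** Syllables are 50 ms Hann-windowed noise bursts —
  chosen to give unambiguous envelope peaks — placed flush with voiced
  segment edges (so an inserted pause is acoustically exactly a pause,
  with no silent margins bleeding into it), above a configurable noise
  floor (default −60 dB).
* **2IFC choices** arise from a latent Gaussian preference over rates
  plus Gaussian utility noise (default SD 0.7, set so that the choice
  probabilities stay in the quasi-linear range where the count profile
  is an affine image of the preference curve and the fitted peak/FWHM
  are unbiased); exact ties, including noise-free self-pairs, fall to a
  fair coin, since no tie rule is otherwise defined.
* **Comprehension trials** follow a logit-linear model with crossed
  random intercepts and a rate slope; default odds ratios (0.65 per SD
  of rate, 1.19 motor rate, 1.34 synchrony, 1.20 working memory, 0.84
  perplexity, …) reproduce the qualitative effect pattern of interest,
  and random-effect SDs (0.5 / 0.3 / 0.15) are plausible mid-range
  values for behavioural cohorts.

What the generator does *not* emulate: acoustic realism of whispered
speech (no formants, no breath noise structure), listener-specific
lapses, serial dependence between trials, or item difficulty beyond the
random intercept. Passing tests therefore show that the estimators
recover the truth of *this* generative family at realistic parameter
settings — they cannot certify performance on recordings whose envelope
statistics differ grossly (e.g. heavily reverberant audio).

## Numerical choices

* **Zero-phase filtering** applies the squared magnitude response of the
  Butterworth band-pass in the frequency domain. This is the exact
  forward–backward filter without edge transients from state
  initialization, it commutes with time reversal to machine precision,
  and it removes DC exactly. Its one artefact — circular wrap-around at
  the record edges — is handled by trimming 1 s from each end of every
  phase series before PLV computation (configurable; the trim also
  discards Hilbert edge effects).
* **Resampling** to 100 Hz uses Fourier-method resampling (spectrum
  truncation), i.e. an ideal anti-aliasing filter. Envelopes are
  effectively band-limited far below the 50 Hz target Nyquist, so this
  is exact for the signals at hand; tiny negative excursions from ideal
  filtering are clipped to zero to preserve envelope nonnegativity.
* **k-means in 1-D** is solved with 50 restarts and verified in the test
  suite against an exhaustive contiguous-partition oracle (the optimal
  1-D 2-means is a threshold split, so small instances can be solved
  exactly). Cohorts of exactly two participants bypass `stats::kmeans`
  (which requires k < n) with the trivial optimum. Identical PLVs raise
  a degenerate-clustering error rather than returning an arbitrary
  split.
* **Gaussian preference fits** start at the empirical mode with a
  moment-based width, bounded μ ∈ [grid min − 1, grid max + 1];
  non-convergence raises a classed fit-failure error with the offending
  distribution attached, never a silent NA. At least three nonzero grid
  points are required.
* **Degenerate inputs** are first-class: all-silent audio yields zero
  nuclei and an undefined (NA, flagged) rate; empty trial lists,
  zero-probability tokens, out-of-pair choices, rank-deficient designs
  and out-of-range p-values all raise classed errors naming the
  offender.

## Problem sizes

The shipped demonstration and validation sizes are chosen to exercise the
study scale where it matters while keeping a full run on one CPU
comfortable: the cohort demo uses 82 participants × 240 items with two
80 s synchronization runs each, two 30 s production trials at 4 kHz, and
10 repetitions per 2IFC pair; estimator calibrations use 60–200
replicates per condition; the mixed-model calibration study uses 100
cohorts at the full 82 × 240 scale with `nAGQ = 0`. The end-to-end demo
completes in about 90 s; the whole validation suite in well under ten
minutes.

## Known limitations

* The cochlear envelope is a generic gammatone/ERB implementation; exact
  agreement with any specific toolbox's envelope is not claimed.
* The HIGH/LOW split inherits k-means' assumption of two groups;
  cohorts sampled from a unimodal distribution will still be split, and
  only the silhouette diagnostic flags it.
* Perplexity from the add-k n-gram provider is a plumbing stand-in;
  scientific use should plug in a serious language model through the
  provider interface.
* The GAMM-style smooth analysis of percent-correct intelligibility data
  is out of scope; the package offers the logistic mixed model and
  rate-binned Wilson summaries instead.
* Wald inference and the `nAGQ = 0` approximation are calibrated here at
  the 82 × 240 scale (pooled CI coverage ≈ 95%); much smaller cohorts
  or near-boundary variance components may need profile or bootstrap
  intervals.
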