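---
title: "Speech markers of mood symptom severity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech markers of mood symptom severity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mood episodes in bipolar disorder leave measurable traces in speech: depressive
states are associated with longer pauses, longer latency before speaking,
fewer words and rougher voice quality, while manic states show pressured,
faster speech. `speechmarkers` implements the full analysis chain from a mono
recording of a prose-recall task plus a word-timestamped transcript to
clinically interpretable indices and severity models:

1. **Conversational timing** — phonation/silence segmentation, speech rate,
   phonation and silence ratios.
2. **Voice quality** — fundamental frequency (F0) statistics, the jitter and
   shimmer perturbation families, and the mean harmonics-to-noise ratio (HNR).
3. **Language and semantics** — word count, story-match count, latency time,
   mean intraword time, and the word mover's distance (WMD) between the
   retelling and the reference story.
4. **Statistics** — Spearman/Pearson correlation with MADRS and YMRS totals,
   sex-stratified subgroup analyses, severity-group rank tests, and random
   forest regression of symptom totals under 5-fold nested cross-validation
   with Shapley attributions.

Because clinical recordings cannot be redistributed, the package ships a
synthetic-data module that generates (i) voiced-speech surrogates with exactly
known perturbation ground truth and (ii) cohorts with configured
feature–symptom effect sizes. Every estimator in the package is validated
against these constructions.

## The synthetic voice model

A voiced sound is simulated as a train of excitation pulses. Per cycle $i$ the
period and pulse amplitude are drawn as

$$T_i = \frac{1}{f_0}\,(1 + \sigma_J z_i), \qquad
  A_i = A_0\,(1 + \sigma_S w_i), \qquad z_i, w_i \overset{iid}{\sim} N(0,1),$$

where $\sigma_J$ is the relative jitter level and $\sigma_S$ the relative
shimmer level. A draw that would produce $T_i \le 0$ is rejected and redrawn
(the count is reported; at realistic $\sigma_J \le 0.05$ this is essentially
never triggered). Each pulse is rendered as an exponentially damped sinusoid
with carrier $2 f_0$ and decay constant $\tau = 1/(5 f_0)$: the kernel decays
to under 1% within one period, so per-cycle waveform peaks remain proportional
to the drawn $A_i$, and the pulse-rate periodicity (not the carrier) dominates
the autocorrelation. White Gaussian noise is scaled to meet the requested SNR
in expectation.

The choice of iid multiplicative perturbations makes the estimators'
targets analytic: for iid normal perturbations the expected local jitter is

$$E\!\left[\frac{\text{mean}|T_i - T_{i-1}|}{\text{mean}\,T}\right]
 \approx \frac{2\sigma_J}{\sqrt{\pi}},$$

since the difference of two iid $N(0, \sigma_J^2)$ variables is
$N(0, 2\sigma_J^2)$ and a folded normal has mean $\sigma\sqrt{2/\pi}$. The
same holds for shimmer. The test suite checks the full extraction chain
(pitch → cycle epochs → perturbation measures) against this closed form over
seeded trains at $\sigma \in \{0.005, 0.01, 0.02\}$, and the cycle-level
ground truth (epochs, periods, amplitudes, signal and noise components) is
returned exactly as drawn so any stage can be checked in isolation.

Real speech differs from this surrogate in ways that matter for
interpretation: there are no formants, no amplitude envelopes at syllable
scale, no voiced/unvoiced consonant structure, and no ASR transcription
errors. Passing the recovery tests demonstrates that the estimators are
correct for quasi-periodic signals with known perturbations — not that they
are robust to every recording condition in the field.

## Segmentation into phonation and silence

Frame RMS intensity is computed on 50 ms windows at a 10 ms hop. A frame is
silent when its intensity falls more than a threshold (default 25 dB) below
the peak intensity, taken as the 99.5th percentile of frame intensities
rather than the maximum so that a single click cannot shift the reference.
Because a *relative* threshold cannot label a recording that is silence
throughout, frames below an absolute floor (default −60 dBFS) are silent
regardless. Runs shorter than `min_silent_s` and then `min_sounding_s`
(defaults 0.10 s each) are merged into their neighbours.

Frame labels are mapped to time so that a silent interval spans from the
*window start* of its first silent frame to the *window start plus window
length* of its last: a window only reads silent under a deep threshold when it
lies almost entirely inside the pause, so each detected edge is within one
hop (10 ms) of the true edge, which the recovery tests confirm on planned
sessions. Intervals are half-open `[start, end)` and tile the recording
exactly.

Note the direction of the threshold parameter: it is expressed in dB *below
peak*, so raising it lowers the effective cutoff and can only shrink the
silent set. The property tests assert total silence is non-increasing in the
threshold.

Conversational features follow directly: `phonation_over_duration`,
`silence_over_phonation` (reported missing, never infinite, when phonation is
zero), and speech rate in words per second of total speech duration (the
words-vs-syllables choice is encoded in the column name, `speech_rate_wps`).

## Pitch, cycles and voice-quality indices

**Pitch.** Per frame (window $3/\text{floor}$, hop 10 ms) the normalized
autocorrelation is evaluated over lags between `1/ceiling_hz` and
`1/floor_hz` (defaults 75–500 Hz, spanning adult male and female ranges);
local maxima are refined by parabolic interpolation. A perfectly periodic
signal also correlates at period multiples, so candidates are biased by an
octave cost (0.01 per octave below the ceiling) and the final path is chosen
by dynamic programming with an octave-jump transition cost; frames whose best
candidate falls below the voicing threshold (0.45) are unvoiced. All
parameters are exposed.

**Cycle extraction.** Within each voiced run, cycle epochs are located by
peak-picking the waveform at the local period, with parabolic sub-sample
refinement (without it, sample quantization at 16 kHz would swamp jitter at
$\sigma = 0.005$). Cycles implying periods outside `[1/ceiling, 1/floor]` are
dropped, counted, and break the run; periods are never computed across run
breaks or pauses, and perturbation measures pool runs weighted by their cycle
counts.

**Jitter and shimmer** follow the de-facto standard (Praat-compatible)
definitions: `local` (mean absolute consecutive difference over the mean),
`local_abs` (seconds), `rap`/`ppq5` (deviation from 3- and 5-point running
means), `ddp = 3·rap`; shimmer analogously with `local_db`
($\text{mean}\,|20\log_{10}(A_{i+1}/A_i)|$), `apq3/5/11`, `dda = 3·apq3`.
The identities hold to machine precision by construction and are asserted on
extracted sequences. The full variant list is included for completeness even
where an individual study reports only a subset.

**HNR.** Per voiced frame the normalized autocorrelation $r$ at the F0 lag
gives the frame ratio $10\log_{10}(r/(1-r))$ dB, with $r$ clipped to
$[10^{-6}, 1-10^{-6}]$; the index is the mean over voiced frames. For the
synthetic construction the expectation of $r$ at the period lag is
$P_s/(P_s+P_n)$, so HNR equals the injected SNR — the calibration tests
exploit this correspondence at 5, 10 and 20 dB.

**F0 statistics** use the population SD convention (divide by $n$) over
voiced frames, stated explicitly because frame statistics conventions differ.

## Language and semantic features

Tokens are normalized deterministically (lowercase, any non-letter/digit
becomes a separator); no lemmatization or stop-word removal is applied, so
the story-match count is type-level set membership after normalization.
Latency is first-word onset minus the task clock origin. Mean intraword time
uses onset-to-onset intervals by default — the average production time per
word including articulation — with the offset-to-next-onset (gap) convention
available behind a switch; both carry the same qualitative relation to
depressive (slower) and manic (faster) speech.

WMD treats both documents as normalized bag-of-words mass distributions over
their in-vocabulary tokens and returns the minimal cumulative transport cost
with Euclidean ground distance between embedding vectors. The transport
problem is solved exactly: masses are scaled to integer units and the
successive-shortest-path min-cost-flow algorithm is run on the bipartite
residual graph, so no iterative tolerance enters the result. The tests
compare it against an exhaustive enumeration oracle on toy instances and
check the metric properties (identity, symmetry, nonnegativity, triangle
inequality spot-checks). Out-of-vocabulary tokens are dropped and counted —
deterministic and auditable; an embedding table is therefore a required
input and is never bundled.

## The synthetic cohort model

Per target (MADRS or YMRS) a latent standard normal $Z_t$ drives the symptom
total through the quantile function of a negative-binomial marginal, clamped
to the instruments' 0–60 range. The defaults (MADRS: $\mu = 18$, size 1.1;
YMRS: $\mu = 12$, size 0.5) produce right-skewed totals with median/IQR close
to 13/20 and 5/15 respectively — the moderate-depression, low-mania profile
typical of an outpatient bipolar cohort. Each configured feature is a
unit-variance normal correlated with $Z_t$ at the level
$r = 2\sin(\pi\rho_s/6)$ that yields the requested population Spearman
correlation $\rho_s$ under the Gaussian copula. Sex is assigned 50/50; for
features with a sex modifier the latent correlation is multiplied by the
modifier in females, reproducing sex-dependent correlation strength.
Residual feature noise (`noise_sd`) defaults to zero so that sample Spearman
correlations converge to their configured targets as $n$ grows (the recovery
tests use $n = 2000$ with a ±0.05 band); any added noise attenuates the
realized correlation below the target, which is the intended reading of the
configuration. Discretization of the totals introduces ties and a small
(<2%) attenuation, well inside the test band.

## Association and model layers

Correlations are pairwise-complete with average-rank ties for Spearman and
two-sided p-values; cells with fewer than 4 complete pairs or zero variance
are missing with a reason, never silently dropped. Group differences at the
clinical cutoffs (MADRS ≥ 19, YMRS ≥ 20, both inclusive) use the two-sided
Mann–Whitney test — exact when both groups are small and tie-free, normal
approximation with tie correction otherwise — since the skewed totals rule
out t-tests as a default. No multiple-testing correction is applied by
default; a Benjamini–Hochberg column is available behind an explicit call.

The severity models are random forests under 5-fold nested cross-validation:
the outer folds estimate generalization, an inner 3-fold grid search (trees
{200, 500} × depth {unbounded, 5} × min node size {1, 3}, scored by MSE)
selects hyperparameters on each outer training set, and the winner is refit
on the full outer training set. Outer folds are stratified by target quartile
— with cohorts of a few dozen rows, unstratified folds can end up with
near-constant test targets and erratic $R^2$ — and stratification is
switchable. Features enter unscaled (forests are invariant to monotone
feature scaling). Sex adjustment appends a 0/1 indicator (female = 0,
male = 1) as a predictor. Rows with missing features are dropped listwise
with a reported count; imputation would inject structure the analysis cannot
verify. Every random choice derives from a single integer seed, and repeated
runs are identical.

Shapley attributions use permutation sampling against a background sample:
for each sampled permutation and background row, features are switched from
background to explained values in permutation order and each feature is
credited with the prediction change at its switch. The telescoping sum makes
local additivity exact — per explained row the attributions sum to
`prediction − base_value` with `base_value` the mean prediction over the
background sample — while sampling error only affects how the total is shared
among features. Defaults (8 permutations × 20 background rows) keep the
symmetry error of duplicated features within a few percent; both knobs are
exposed, and tests verify additivity at $10^{-6}$, the single-feature edge
case, and that a planted signal feature ranks first by mean absolute
attribution in at least 8 of 10 seeded runs.

## Numerical and engineering choices

- Audio I/O is mono 16-bit PCM WAV, read and written by a minimal RIFF
  chunk walker; samples are rescaled to $[-1, 1]$ and quantization error is
  bounded by $1/32767$.
- Intervals are half-open `[start, end)` seconds from recording start; the
  tiling invariant (sum of interval lengths = duration within one hop) is
  asserted.
- Degenerate inputs are contracts, not crashes: all-unvoiced tracks give
  missing voice-quality fields with reason codes; zero phonation gives a
  missing silence/phonation ratio; empty transcripts give missing timing
  scores; an empty side after OOV filtering gives a missing WMD with OOV
  counts.
- Pipeline outputs embed the MD5 hash of the resolved configuration
  (excluding the output directory) instead of timestamps, so a rerun into a
  clean directory is byte-identical — asserted end to end on a six-participant
  synthetic manifest.
- Per-participant failures in a pipeline run are isolated: the row is
  flagged, the error recorded in the QC report, and all other participants
  are unaffected.

## Problem sizes used in validation

The shipped validation exercises the chain at sizes chosen to give stable
statistics on a single CPU: ~50 two-second pulse trains for perturbation
recovery, 20 trains across 90–350 Hz for pitch accuracy, 20 planned sessions
for segmentation, 100 toy document pairs against the exhaustive transport
oracle, cohorts of $n = 2000$ for correlation recovery and $n = 200$ for the
model-layer signal/noise contrast.

## Known limitations

- The pulse-train surrogate does not test robustness to formant structure,
  reverberation, compression artefacts, or ASR word-boundary errors.
- The pitch tracker is tuned for sustained quasi-periodic phonation; creaky
  or diplophonic voice would need different candidate generation.
- Story matching is type-level and unlemmatized; morphologically rich
  languages will under-count matches relative to a lemmatized variant.
- The exact transport solver is polynomial but not optimized for very long
  documents; at prose-recall scale (hundreds of unique tokens) it is
  comfortably fast.
- Severity models are cross-sectional regressions; no longitudinal or causal
  claims are supported.
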