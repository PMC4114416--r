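---
title: "Methods: HMM keyword spotting for ambulatory cough monitoring"
author: "coughSpot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HMM keyword spotting for ambulatory cough monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adolescents with asthma under-report and mis-perceive their own symptoms,
and conventional self-monitoring (diaries, peak-flow meters) suffers from
poor adherence. An ambulatory monitor that listens continuously, counts
cough events automatically, and relates them to activity and medication use
gives both the patient and the clinician an objective symptom record.
`coughSpot` implements such a monitor as desk-scale software: continuous
audio in, timestamped cough events, hourly summaries, activity scores,
a medication diary, and the validation and acceptance statistics used to
judge such a device.

## The detection model

Detection follows the standard keyword-spotting recipe from speech
recognition:

1. **Front end.** Audio (16 kHz mono) is cut into 25 ms frames at a 10 ms
   hop. Per frame: pre-emphasis (0.97), Hamming window, power spectrum,
   26-channel mel filterbank, log, DCT-II. The first 13 cepstra are kept,
   with c0 replaced by the frame log-energy; delta and delta–delta
   coefficients are appended (D = 39). Processing is blocked into 6 s
   segments — the device's unit of work — and cepstral means are removed
   per segment.

2. **Acoustic models.** Each sound class is a left-to-right HMM with
   self-loops (entry into state 1, exit from the last state) and
   diagonal-covariance Gaussian-mixture emissions: 5 states x 2 mixtures
   for the cough keyword, 3 states per filler. Fillers absorb everything
   that is not a cough. Models are trained by Baum–Welch; initialisation
   segments each training sequence uniformly across states and splits each
   state's frames into mixtures by seeded k-means. All probability
   arithmetic is in the log domain; the per-frame lattice recursions are
   compiled code.

3. **Decoder.** The models are joined in a loop grammar (any model may
   follow any model). A token-passing Viterbi pass over the composed
   network produces the best-scoring segmentation of each 6 s block into
   labelled spans; maximal cough-labelled spans become events. Decoding is
   exact by default (no beam); a log-domain beam is available. Exact score
   ties resolve to the lowest state index, so decoding is deterministic.

4. **Post-processing.** Within a segment, cough spans separated by less
   than 200 ms are merged (intra-cough phase gaps), then spans shorter than
   60 ms are dropped (below a cough's explosive phase). Merging before
   dropping keeps the event count monotone non-increasing in the
   minimum-duration threshold; the reverse order can split one merged
   event into two when a bridging span is removed, which is why this
   order was chosen.

## The insertion penalty and its calibration

A loop grammar with no insertion cost will happily insert the keyword
model wherever a transient marginally favours it; the false-alarm rate is
then far above anything a deployed monitor could tolerate. The network
therefore charges a log-domain penalty at every inter-model transition.
This is the detector's operating point on the sensitivity/false-alarm
trade, and it is fixed the way such operating points normally are: on
*development* data. `trainNetwork()` generates seeded cough-free
development scenes from the same generators used for training material
(development seeds are derived from the training seed and disjoint from
any evaluation seeds), decodes them under a penalty grid (0 down to -550), and
keeps the mildest penalty whose development false-alarm rate is at most 1
event/hour — a deliberate margin under the 2/hour the study's device
reported in the field. Filler mixtures are larger (6 per state) than the
keyword's (2): fillers must tile heterogeneous background classes, and
richer fillers raise the background's own score, widening the margin the
penalty works with. Evaluation audio is never consulted during
calibration.

## Audit retention

Mirroring the device's validation protocol, every segment containing a
detected event is retained for audit; event-free segments are retained at
random with probability 0.05 (seeded draws, one per empty segment, in
order). Retained segments can be exported as 6 s WAV clips with a CSV
manifest, which is what makes manual confirmation of true/false positives
possible.

## The synthetic study conditions

No recordings are distributed with the original study, so the package
carries seeded generators for every input, and these generators define the
benchmark conditions:

* **Coughs** are band-filtered noise bursts (roughly 250–3200 Hz), 50–350
  ms, sharp attack (5–15 ms) with exponential decay, occasionally followed
  by a short voiced tail — the literature-typical parameterisation of the
  explosive cough phase.
* **Background** is a continuous bed of mains-style hum (120 Hz plus
  harmonics), speech-like babble (a few harmonic voices with drifting
  pitch, formant-band filtering and 3–4 Hz syllabic modulation) and
  broadband noise, with impulsive door slams (low-frequency thump plus
  resonant ring, about 2 per minute) — door slams and speech being the
  confusers the study itself named.
* **Scenes** embed a requested number of coughs without overlap, each
  inside a single 6 s segment by default (a flag allows
  boundary-straddling placement to probe the known segment-boundary
  limitation), and scale the background so that mean within-event cough
  power over background power hits the requested SNR. The benchmark uses
  10 dB — loud enough that a collar microphone would capture it, quiet
  enough that babble and slams genuinely compete.
* **Training corpora** pair tightly trimmed cough clips (50 ms context,
  mixed with the bed at the scene SNR — multi-condition training) with 1 s
  background clips cycling over bed, bed-plus-slam, and near-silence
  classes, 200 of each by default.
* **Activity traces** are per-minute scores: mostly near zero with random
  active bouts (calibrated to an ambulatory mean below 1 and SD near 3 on
  the 0–24 scale), plus a configurable coupling times the number of coughs
  in the minute, capped at 24.
* **Survey tables** follow a parallel-items model — latent score plus item
  noise, discretised to the 1–5 response scale — with the latent weight
  calibrated by numeric integration so the *post-discretisation*
  inter-item correlation hits the requested value; Cronbach's alpha then
  approaches k\\(\rho\\)/(1+(k−1)\\(\rho\\)).

What the generators do **not** emulate: real vocal-tract variability
between and within patients, room reverberation, microphone handling
noise, overlapping speakers, or wheeze (which the source device abandoned
for lack of trainable data and which is out of scope here). A detector
passing the synthetic benchmark is therefore shown to implement the
method correctly at a plausible operating point — not to be clinically
validated.

## Activity scoring

The device's 0–24 activity score is undocumented, so the package defines
it as a capped, scaled mean absolute deviation: per complete minute, the
MAD of the acceleration magnitude about its minute mean, times 12π, capped
at 24. The constant maps a 1 g sinusoidal oscillation (vigorous motion) to
the cap, since a sine of amplitude A has MAD 2A/π; the statistic is
monotone in movement intensity and bounded as the device's printed range
requires. Cough–activity correlation is plain Pearson with the t-transform
p-value, paired per minute by default (the device's activity granularity),
hourly on request.

## Survey statistics

The 7-item acceptance scale is scored by summation (range 7–35); totals of
28 or more — "agree" or better on every item — flag satisfactory
acceptance. Per-item agreement pools responses of 4 and 5 over the item's
non-missing denominator (pairwise deletion); Cronbach's alpha uses
unbiased variances over listwise-complete rows, matching the different
denominators such instruments report per item while keeping alpha
well-defined. Percentages are kept at full precision with display rounding
left to the caller.

## Numerical choices

* Log-sum-exp throughout; -Inf-safe recursions.
* Variance flooring at 1e-3 per dimension in every M-step; mixture weights
  floored at 1e-10 and renormalised.
* Frame powers clamped at 1e-10 before logs so silence stays finite.
* EM stops on relative log-likelihood improvement below 1e-5 or 25
  iterations; a decrease beyond 1e-6 slack raises an error naming the
  iteration.
* Trailing partial frames are dropped (frames are model inputs); trailing
  partial segments are kept (segments are containers).
* Event matching for validation is greedy in time order on event midpoints
  with a 0.5 s tolerance; on this interval structure greedy matching
  attains the maximum one-to-one matching (verified in tests against a
  brute-force oracle).
* Model serialisation writes doubles at full precision; -Inf log
  probabilities encode as JSON nulls, so save/load round-trips are
  lossless.

## Problem sizes

The shipped benchmark trains on 200 cough and 200 background clips and
evaluates on ten 600 s scenes of 30 coughs each (sensitivity) plus ten
720 s cough-free scenes (false alarms), with three 600 s development
scenes for penalty calibration — about 5.5 hours of audio end to end,
chosen as comfortable desk-scale sizes for a single CPU. Unit tests use
smaller corpora (60 clips) and shorter scenes; parameter-recovery and
reliability simulations use 200 sequences of 50 frames and 5000 survey
respondents respectively.

## Known limitations

* Events cannot cross 6 s segment boundaries, because segments decode
  independently — the same limitation as the device's block processing.
  The scene generator can place boundary-straddling coughs to quantify the
  effect.
* One cough per decoded span: a rapid volley merged by the 200 ms rule
  counts once.
* The activity score and the cough acoustic model are declared package
  definitions, not reconstructions of the device's undocumented internals.
* Whether the study computed sensitivity at event or segment granularity
  is not stated; event granularity is assumed throughout.
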