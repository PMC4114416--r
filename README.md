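# coughSpot

Ambulatory asthma monitoring hinges on counting symptoms a patient cannot
reliably count themselves. `coughSpot` is a desk-scale R implementation of
an automated cough monitor: continuous single-channel audio is digitised
into mel-cepstral feature vectors and decoded, six seconds at a time, by a
token-passing Viterbi decoder over a loop grammar of hidden Markov models —
one left-to-right cough *keyword* model and several *filler* models that
absorb background noise, speech-like babble and door slams. Decoded
cough-labelled spans become timestamped events; segments containing events
(plus a random sample of event-free segments) are retained for audit;
events aggregate into the hourly bar-chart a patient would see alongside an
accelerometer-derived activity line (0–24 scale) and a medication diary.
The package also implements the validation statistics for such a detector
(greedy one-to-one event matching, sensitivity, false positives per hour,
rater percent agreement) and the acceptance-survey statistics
(7-item scale scoring with a satisfaction cutoff of 28, per-item agreement,
Cronbach's α, item–companion correlations).

The core decoder solves, per 6-s block of frames $o_{1:T}$,

$$\hat{\ell}_{1:T} \;=\; \arg\max_{\ell_{1:T}}\;
\sum_t \Big[\log b_{\ell_t}(o_t) + \log a_{\ell_{t-1}\ell_t}\Big]
\;+\; n_{\text{ins}}\,\pi_{\text{loop}},$$

where states range over all models' states, cross-model transitions pay an
insertion penalty $\pi_{\text{loop}}$, and emissions $b$ are diagonal-
covariance Gaussian mixtures trained by Baum–Welch. Since no study audio is
deposited anywhere, a seeded synthetic module generates every input the
pipeline consumes — parametric cough bursts embedded in babble/hum/slam
background at controlled SNR with exact ground-truth labels, coupled
activity traces, and survey tables with controllable reliability — and the
shipped benchmark measures the detector against the published operating
point (sensitivity ≥ 70 %, false positives ≤ 2/hour).

## Worked example

```r
library(coughSpot)

# 1. seeded training material: 60 noisy cough clips + 60 background clips
corpus <- synthTrainingCorpus(nCough = 60, nBackground = 60, seed = 7)

# 2. train keyword + filler HMMs; the insertion penalty is calibrated on
#    cough-free development audio generated from the training seed
net <- trainNetwork(corpus, seed = 7)
net

# 3. a two-minute labelled scene: 10 coughs over babble+hum+slams at 10 dB
scene <- synthScene(sceneSpec(durationS = 120, nCoughs = 10, snrDb = 10,
                              seed = 42))
res <- detectEvents(scene$recording, net, detectionConfig(seed = 1))
events <- collectEvents(res)
head(events, 3)

# 4. score against the generator's ground truth
m <- matchEvents(events, scene$truth, tolS = 0.5)
c(tp = m$tp, fn = m$fn, fp = m$fp)
sensitivity(m); fpPerHour(m, 120)
```

This prints (seeds as above):

```
RecognitionNetwork: keyword 'cough' + fillers [background, slam, quiet], loop penalty -300
  start_s  end_s segment_index log_score
1   12.23 12.555             2 -1058.361
2   24.78 25.305             4 -1188.848
3   50.96 51.365             8 -1290.008
tp fn fp
10  0  0
[1] 1
[1] 0
```

i.e. all ten embedded coughs are recovered (sensitivity 1.0) with no false
positives in the two minutes. Survey-side,
`cronbachAlpha(synthSurvey(5000, 7, rho = 0.33, seed = 1)[, -1])` returns
`0.784`, recovering the parallel-test closed form 7ρ/(1+6ρ) ≈ 0.78 — the
internal-consistency level the acceptance scale reported.

A thin command-line front end over the same functions lives in
`inst/scripts/coughspot.R` (`detect`, `evaluate`, `survey`, `simulate`,
`report`).

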