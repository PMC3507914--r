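---
title: "Fasciculation surveillance with HD-SEMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fasciculation surveillance with HD-SEMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpwatch)
```

## The question and the statistic

A fasciculation potential (FP) is the electrical signature of a
spontaneous motor-unit discharge in a relaxed muscle. When a
high-density surface EMG (HD-SEMG) array is used to screen a muscle for
FPs, the practical question is how long to record before concluding
that FPs are absent. `fpwatch` answers it with an interval statistic:
given FP occurrence times $t(1) < t(2) < \dots < t(N)$ in a recording,
the order-$i$ intervals are

$$I_i(n) = t(n+i) - t(n), \qquad 1 \le n \le N - i,\; i = 1,\dots,5,$$

each the waiting time within which the next $i$ FPs occurred. The
empirical cumulative distribution of the pooled $I_i$ values is then
read as a function of observation duration $T$: the probability that
$i$ FPs will have been observed within a window of length $T$.
`duration_for_probability()` inverts the curve; its value at $p = 1$ is
the longest wait for $i$ FPs seen anywhere in the data, i.e. the
observation time after which absence of FPs becomes convincing.

Three conventions matter and are fixed throughout:

* **Right continuity.** The probability at $T$ counts intervals
  $\le T$, so the curve reaches exactly 1 at the maximum pooled
  interval and `duration_for_probability(curve, 1)` equals that
  maximum exactly (the curve grid always ends on it).
* **Censoring.** The open interval from the last FP to the end of the
  recording is excluded — the formula spans only $n \le N - i$. This
  biases the longest intervals slightly downward; long recordings
  mitigate it, which is why the simulated cohort uses durations of
  several minutes.
* **Pooling.** "The whole dataset" can mean every interval from every
  muscle with equal weight (`pooling = "all_intervals"`, the default)
  or one value — the maximum — per muscle (`"per_muscle_max"`, for
  sensitivity analysis). The two differ materially: all-interval
  pooling weights high-rate muscles in proportion to their interval
  counts, so cohort curves rise faster than a per-muscle average
  would. Both modes are first-class; neither is claimed to be uniquely
  correct, and analyses of heterogeneous cohorts should report both.

Skewness of the order-1 intervals is reported per muscle using the
Fisher–Pearson adjusted estimator $\sqrt{n(n-1)}/(n-2)\,g_1$; it is set
to `NA` below 4 events (3 intervals) rather than silently zeroed, and
defined as 0 for perfectly regular trains (zero variance).

## The renewal-process generator

`generate_event_train()` draws i.i.d. inter-event intervals — a renewal
process — with exponential, gamma or lognormal distribution. A renewal
process is the simplest generator consistent with summarising
spontaneous activity purely by its interval distribution; it ignores
serial correlation and slow non-stationarity of real fasciculation,
which is a stated limitation, not an oversight.

Defaults of the synthetic cohort (`study_config()`) emulate the
clinical recording conditions the package targets:

* 29 muscles cycling through two grid-array muscles (first dorsal
  interosseous, thenar; 64 electrodes, 8×8, 4 mm pitch) and one
  linear-array muscle (biceps brachii; 20 bars, 5 mm pitch);
* FP rates log-uniform on 3.5–139 events/minute — the reported clinical
  range spans 40-fold, and a log-uniform draw spreads muscles evenly
  across that spread rather than clustering at high rates;
* gamma-distributed intervals with shape 3.5: theoretical skewness
  $2/\sqrt{3.5} \approx 1.07$, matching the interval skewness of about
  1 observed in fasciculating muscles (an exponential process, skewness
  2, is too irregular);
* recording durations uniform on 215–764 s;
* 2–5 dead (disconnected) channels per recording;
* sampling at 2 kHz with a 20–500 Hz system band.

Event amplitude is a free modelling choice — surface FP amplitudes for
these muscles are not well characterised — so `fp_waveform()` defaults
to a 150 µV biphasic kernel (first derivative of a Gaussian, 10 ms
support) with exponential spatial decay (length constant 10 mm,
normalised so the nearest channel carries the nominal amplitude) and
0.2 ms per-channel latency jitter; all configurable. Noise is white
Gaussian filtered to the 20–500 Hz system band and scaled to an exact
per-channel RMS. Coincident events from different simulated units
closer than 1 ms are merged in the ground truth, because the analysis
counts FPs regardless of waveform or unit of origin.

What passing tests on this generator do *not* show: robustness to
motion artifact, voluntary-contraction EMG, fibrillation potentials or
other spontaneous activity classes, electrode-skin impedance drift, or
volume-conductor effects beyond a monotone distance decay. The
synthetic benchmark validates the pipeline's arithmetic and its
behaviour under noise, not its clinical sensitivity.

## The detector

`detect()` implements threshold-based spike detection across all
channels:

1. channels flagged dead, plus any channel whose robust noise estimate
   is 0 or more than 10× the median channel noise, are excluded
   (mirroring the practice of disconnecting poor-quality electrodes);
2. each live channel is band-pass filtered 20–500 Hz with a 4th-order
   Butterworth applied forward and backward (zero phase), so detection
   times are not shifted by filter delay;
3. the per-channel threshold is `threshold_k` (default 5) times the
   MAD-based noise sigma (`MAD/0.6745`), which sparse large spikes do
   not inflate — this makes detection exactly invariant to amplitude
   rescaling of the recording;
4. supra-threshold excursions yield one peak time each, excursions
   closer than the refractory period (default 20 ms) merge to the
   larger peak;
5. detections across channels within the coincidence window (default
   10 ms) coalesce into one FP event timed at the globally largest
   per-channel peak (a max, not a mean, so low-amplitude channels
   cannot drag the consensus), and events supported by fewer than
   `min_channels` channels (default 3 on the grid, 2 on the linear
   array, where a source can sit near the array end) are rejected as
   artifacts.

No numeric value of the threshold, window or consensus count is
prescribed by clinical convention; these defaults follow standard
extracellular spike-detection practice and are all exposed in
`detection_config()`. Whether a clinical threshold should be fixed in
µV instead of noise-relative is genuinely open; the noise-relative
choice was made for its scale invariance and is documented as a design
decision, not a reconstruction of any particular laboratory's settings.

One numerical edge case: an idealised noise-free channel has zero MAD
but real activity. Rather than discarding it as dead, the detector
falls back to a threshold of half the channel's absolute maximum
(triggered when the MAD is below $10^{-6}$ of the peak, which also
guards against filter-ringing residue on otherwise silent channels).
Truly silent channels remain dead.

## Numerical choices and degenerate inputs

* Times are 0-based seconds (doubles) from the first sample; event CSVs
  store 6 decimals (1 µs), far below the 0.5 ms sample period.
* The curve grid step defaults to 1 s; the grid always includes the
  exact maximum pooled interval as its last point. Analyses that invert
  the curve near steep regions (e.g. comparing against an analytic
  quantile) should use a finer step — the closed-form tests use 0.1 s.
* Trains with $N \le i$ contribute nothing at order $i$ but are not
  excluded from the cohort; an all-empty pool is an error, never a
  silent zero.
* `pool_and_cumulate` rejects interval sets whose order does not match;
  readers never silently drop channels or events.
* EDF export quantizes to 16 bits over the recording's own range
  (round-trip error bounded by `edf_quantization_step()`); the float32
  native layout round-trips bit-exactly. EDF data records are 1 s, the
  final record zero-padded, with the exact sample count kept in the
  JSON sidecar.

## Verification strategy and problem sizes

The test suite checks the implementation against independent oracles:
a brute-force loop for $I_i$ on 1000 random trains; hand-counted
curves on a four-event train; the renewal-theory closed form (order-$i$
intervals of a Poisson process are Gamma($i$, $\lambda$)) on 200
simulated trains of 600 s at 12/min, including the analytic 95%
quantile $-\ln(0.05)/\lambda$; recovery of $2/\sqrt{\text{shape}}$
skewness from gamma trains averaged over 40 trains of at least 500
events; and a 29-recording signal-level benchmark at SNR 10 (durations
scaled to a tenth of the clinical range to keep the benchmark at desk
scale) where pooled detection F1 must reach 0.99 at ±5 ms and the
curves computed from detected events must agree with ground-truth
curves to within one grid step of observation duration at each target
probability. Structural invariants — curve monotonicity, terminal
probability 1, order dominance $I_{i+1}(n) \ge I_i(n)$ per paired
index, time-rescaling equivariance, amplitude-scale invariance of
detection — are asserted exactly on every run.

## Known limitations

The renewal model has no serial dependence; the simulator's spatial
model is a monotone decay, not a volume conductor; detection assumes a
stationary noise floor per channel; censored tail intervals bias the
p = 1 durations slightly downward; and cohort-level curves depend on
the pooling convention, which must be reported alongside any quoted
observation duration.
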