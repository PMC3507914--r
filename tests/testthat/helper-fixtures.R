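# Shared fixtures: small geometries and recordings that keep unit tests
# fast while exercising the same code paths as full-size arrays.

small_grid <- function() array_geometry("grid", n_channels = 16, pitch_mm = 4)

# Biphasic (Gaussian-derivative) pulse centred at `centre_s`, peak
# amplitude `amp`, on an otherwise silent trace.
biphasic_pulse <- function(n_samples, sample_rate, centre_s, amp = 10,
                           width_ms = 10) {
  tt <- (seq_len(n_samples) - 1) / sample_rate - centre_s
  sig <- width_ms / 6000
  k <- -tt * exp(-tt^2 / (2 * sig^2))
  k / max(abs(k)) * amp
}

# Quick synthetic recording on the small grid.
quick_recording <- function(rate = 20, duration = 30, snr = 10, seed = 11,
                            jitter_sd_ms = 0.2, dead = integer(0),
                            shape = 3.5) {
  spec <- renewal_spec("gamma", mean_rate = rate, shape = shape, seed = seed)
  truth <- generate_event_train(spec, duration)
  wf <- fp_waveform(jitter_sd_ms = jitter_sd_ms)
  rec <- synthesize_recording(truth, small_grid(), wf,
                              noise_rms = wf$amplitude_uv / snr,
                              dead_channels = dead, seed = seed + 1)
  list(rec = rec, truth = truth)
}

# Brute-force order-i intervals: explicit loop over the printed formula.
brute_force_intervals <- function(times, i) {
  n <- length(times)
  if (n <= i) return(numeric(0))
  out <- numeric(n - i)
  for (k in seq_len(n - i)) out[k] <- times[k + i] - times[k]
  out
}

# Two-sided Kolmogorov-Smirnov distance between a sample and a CDF.
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  fx <- cdf(x)
  max(abs(seq_len(n) / n - fx), abs((seq_len(n) - 1) / n - fx))
}
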