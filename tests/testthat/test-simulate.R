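# Renewal-process train generation and multi-channel synthesis.

test_that("renewal trains are reproducible, bounded, and correctly rated", {
  spec <- renewal_spec("exponential", mean_rate = 12, seed = 1)
  tr1 <- generate_event_train(spec, 600)
  tr2 <- generate_event_train(spec, 600)
  expect_identical(tr1, tr2)

  expect_true(all(tr1$event_times >= 0 & tr1$event_times <= 600))
  expect_true(all(diff(tr1$event_times) > 0))
  # expected 120 events, sd sqrt(120) for the Poisson case
  expect_lt(abs(length(tr1$event_times) - 120), 3 * sqrt(120))

  # vanishing observation window
  tiny <- generate_event_train(renewal_spec("exponential", 60, seed = 4),
                               duration = 1e-4)
  expect_length(tiny$event_times, 0L)

  expect_error(renewal_spec("exponential", mean_rate = -2), "positive")
  expect_error(renewal_spec("gamma", mean_rate = 5, shape = 0), "positive")
  expect_error(generate_event_train(spec, duration = 0), "positive")
})

test_that("interval skewness matches the distribution's closed form", {
  # exponential: theoretical skewness 2
  pooled_exp <- unlist(lapply(1:60, function(s) {
    tr <- generate_event_train(renewal_spec("exponential", 12, seed = s), 600)
    diff(tr$event_times)
  }))
  expect_gt(length(pooled_exp), 5000)
  expect_equal(sample_skewness(pooled_exp), 2, tolerance = 0.15)

  # gamma shape 4: 2/sqrt(4) = 1
  tr <- generate_event_train(renewal_spec("gamma", 12, shape = 4, seed = 1),
                             3600 * 10)
  expect_equal(sample_skewness(diff(tr$event_times)), 1, tolerance = 0.1)

  expect_identical(theoretical_skewness(renewal_spec("exponential", 1)), 2)
  expect_identical(theoretical_skewness(renewal_spec("gamma", 1, shape = 4)), 1)
})

test_that("mean empirical rate over many trains matches the spec rate", {
  rates <- vapply(1:100, function(s) {
    tr <- generate_event_train(renewal_spec("exponential", 24, seed = 1000 + s),
                               600)
    length(tr$event_times) / 600 * 60
  }, numeric(1))
  expect_lt(abs(mean(rates) - 24) / 24, 0.02)
})

test_that("synthesis places spatially attenuated kernels at event times", {
  geom <- small_grid()
  wf <- fp_waveform(jitter_sd_ms = 0)

  # no events, no noise -> silent live channels
  silent <- synthesize_recording(ground_truth(numeric(0), integer(0), 2),
                                 geom, wf, noise_rms = 0, seed = 1)
  expect_true(all(silent$signal == 0))
  expect_equal(silent$duration, 2)

  # one event at t = 1.0 s, source at a known electrode
  src <- matrix(geom$channel_positions[6, ], nrow = 1)
  rec <- synthesize_recording(ground_truth(1.0, 1L, 2), geom, wf,
                              noise_rms = 0, source_positions = src)
  peaks <- apply(abs(rec$signal), 1, max)
  peak_t <- apply(abs(rec$signal), 1, which.max) / rec$sample_rate
  expect_equal(max(peaks), wf$amplitude_uv)
  expect_equal(which.max(peaks), 6L)
  expect_true(all(abs(peak_t - 1.0) <= wf$duration_ms / 1000 / 2))
  # amplitude ordering follows distance from the source
  d <- sqrt(colSums((t(geom$channel_positions) -
                       geom$channel_positions[6, ])^2))
  expect_true(all(diff(peaks[order(d)]) <= 1e-9))

  # dead channels are flatlined and flagged
  dead <- synthesize_recording(ground_truth(1.0, 1L, 2), geom, wf,
                               noise_rms = 5, dead_channels = c(2, 9),
                               source_positions = src, seed = 3)
  expect_false(any(dead$live_mask[c(2, 9)]))
  expect_true(all(dead$signal[c(2, 9), ] == 0))
  expect_true(all(abs(dead$signal[1, ]) > 0))

  # validation
  expect_error(synthesize_recording(ground_truth(1.0, 1L, 2), geom, wf,
                                    sample_rate = 800),
               "twice the upper band edge")
  expect_error(synthesize_recording(ground_truth(1.0, 1L, 2), geom, wf,
                                    dead_channels = 99),
               "channel indices")
})

test_that("synthesis is deterministic and additive over disjoint trains", {
  geom <- small_grid()
  wf <- fp_waveform(jitter_sd_ms = 0.3)
  truth <- generate_event_train(renewal_spec("gamma", 30, shape = 3, seed = 2),
                                10)
  r1 <- synthesize_recording(truth, geom, wf, noise_rms = 10, seed = 9)
  r2 <- synthesize_recording(truth, geom, wf, noise_rms = 10, seed = 9)
  expect_identical(r1$signal, r2$signal)

  # superposition (noise- and jitter-free): disjoint sources sum exactly
  wf0 <- fp_waveform(jitter_sd_ms = 0)
  a <- ground_truth(c(0.5, 2.0, 4.0), rep.int(1L, 3), 6)
  b <- ground_truth(c(1.2, 3.1), rep.int(2L, 2), 6)
  src <- geom$channel_positions[c(1, 16), ]
  merged <- merge_ground_truth(a, b)
  sa <- synthesize_recording(a, geom, wf0, noise_rms = 0,
                             source_positions = src)
  sb <- synthesize_recording(b, geom, wf0, noise_rms = 0,
                             source_positions = src)
  sm <- synthesize_recording(merged, geom, wf0, noise_rms = 0,
                             source_positions = src)
  expect_equal(sa$signal + sb$signal, sm$signal)
})

test_that("coincident events from different sources merge into one", {
  a <- ground_truth(c(1.0, 5.0), rep.int(1L, 2), 10)
  b <- ground_truth(c(1.0004, 7.0), rep.int(2L, 2), 10)
  m <- merge_ground_truth(a, b, coincidence_s = 0.001)
  expect_equal(m$event_times, c(1.0, 5.0, 7.0))
  expect_equal(m$source_ids, c(1L, 1L, 2L))
  expect_error(merge_ground_truth(a, ground_truth(1, 1L, 99)),
               "same duration")
})
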