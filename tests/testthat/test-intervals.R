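# Order-i intervals, cumulative curves, and summaries.

test_that("order-i intervals match direct arithmetic and the brute-force oracle", {
  tr <- event_train(c(0, 10, 25, 27), 30)
  expect_equal(compute_intervals(tr, 1)$intervals, c(10, 15, 2))
  expect_equal(compute_intervals(tr, 3)$intervals, 27)
  expect_length(compute_intervals(tr, 4)$intervals, 0L)
  expect_length(compute_intervals(event_train(numeric(0), 10), 1)$intervals, 0L)
  expect_error(compute_intervals(tr, 0), "positive")

  set.seed(8)
  for (rep in 1:25) {
    times <- sort(runif(sample(2:40, 1), 0, 100))
    tr <- event_train(times, 100)
    for (i in 1:5) {
      expect_identical(compute_intervals(tr, i)$intervals,
                       brute_force_intervals(times, i))
    }
  }
})

test_that("cumulative curves count correctly and pool invariantly", {
  s <- compute_intervals(event_train(c(0, 10, 25, 27), 30), 1)
  cv <- pool_and_cumulate(s, 1, grid_step = 1)
  expect_equal(curve_probability(cv, 10), 2 / 3)
  expect_equal(curve_probability(cv, 1), 0)
  expect_equal(cv$probabilities[length(cv$probabilities)], 1)
  expect_equal(duration_for_probability(cv, 1.0), 15)
  expect_equal(duration_for_probability(cv, 0.5), 10)
  expect_error(duration_for_probability(cv, 0), "0, 1")
  expect_error(duration_for_probability(cv, 1.2), "0, 1")

  # two muscles with identical interval sets give the same curve as one
  cv2 <- pool_and_cumulate(list(s, s), 1, grid_step = 1)
  expect_equal(cv2$probabilities, cv$probabilities)
  expect_equal(cv2$durations, cv$durations)
  expect_identical(cv2$n_intervals, 6L)

  # per-muscle-max pooling uses one value per muscle
  s2 <- compute_intervals(event_train(c(0, 3, 6), 10), 1)
  cvm <- pool_and_cumulate(list(s, s2), 1, pooling = "per_muscle_max")
  expect_identical(cvm$n_intervals, 2L)
  expect_equal(duration_for_probability(cvm, 1.0), 15)

  expect_error(pool_and_cumulate(compute_intervals(event_train(1, 10), 1), 1),
               "no intervals at order 1")
  expect_error(pool_and_cumulate(s, 2), "order")
})

test_that("Poisson order-i curves match the Gamma closed form", {
  lambda <- 12 / 60  # events per second
  sets <- lapply(1:40, function(s) {
    tr <- generate_event_train(renewal_spec("exponential", 12, seed = 100 + s),
                               600)
    event_train(tr$event_times, 600, muscle_id = as.character(s))
  })
  for (i in c(1L, 3L)) {
    pooled <- unlist(lapply(sets, function(tr)
      compute_intervals(tr, i)$intervals))
    d <- ks_distance(pooled, function(x) pgamma(x, shape = i, rate = lambda))
    expect_lt(d, 0.03)
  }
  # analytic 95% quantile for one event: -ln(0.05)/lambda = 14.98 s
  i1 <- lapply(sets, compute_intervals, order = 1L)
  cv <- pool_and_cumulate(i1, 1, grid_step = 0.1)
  expect_equal(duration_for_probability(cv, 0.95), -log(0.05) / lambda,
               tolerance = 0.05)
})

test_that("curves are monotone, dominance and rescaling hold exactly", {
  set.seed(12)
  times <- sort(runif(60, 0, 500))
  tr <- event_train(times, 500)

  # paired order dominance: I_{i+1}(n) >= I_i(n)
  for (i in 1:4) {
    a <- compute_intervals(tr, i)$intervals
    b <- compute_intervals(tr, i + 1)$intervals
    expect_true(all(b >= a[seq_along(b)]))
  }

  for (i in 1:5) {
    cv <- pool_and_cumulate(compute_intervals(tr, i), i, grid_step = 2)
    expect_true(all(diff(cv$probabilities) >= 0))
    expect_equal(cv$probabilities[length(cv$probabilities)], 1)
  }

  # time rescaling by c scales intervals, maxima and durations by c
  c_ <- 3.25
  scaled <- event_train(times * c_, 500 * c_)
  for (i in 1:3) {
    expect_equal(compute_intervals(scaled, i)$intervals,
                 compute_intervals(tr, i)$intervals * c_)
  }
  cv <- pool_and_cumulate(compute_intervals(tr, 1), 1, grid_step = 0.5)
  cvs <- pool_and_cumulate(compute_intervals(scaled, 1), 1,
                           grid_step = 0.5 * c_)
  expect_equal(duration_for_probability(cvs, 1.0),
               duration_for_probability(cv, 1.0) * c_)
  expect_equal(duration_for_probability(cvs, 0.8),
               duration_for_probability(cv, 0.8) * c_)
})

test_that("train summaries report rate, skewness and per-order maxima", {
  tr <- event_train(seq(10, 300, by = 10), 300)  # 30 events, equally spaced
  s <- summarize_train(tr)
  expect_equal(s$rate_per_min, 6)
  expect_equal(s$skewness, 0)
  expect_equal(s$max_interval_i1, 10)
  expect_equal(s$max_interval_i5, 50)
  # maxima non-decreasing in order
  expect_true(all(diff(unlist(s[sprintf("max_interval_i%d", 1:5)])) >= 0))

  # too few events: skewness flagged missing, not zeroed
  expect_true(is.na(summarize_train(event_train(c(1, 2, 3), 10))$skewness))
  s0 <- summarize_train(event_train(numeric(0), 60))
  expect_identical(s0$n_events, 0L)
  expect_true(is.na(s0$max_interval_i1))

  # large exponential train: skewness near 2
  tr2 <- generate_event_train(renewal_spec("exponential", 60, seed = 3),
                              60 * 600)
  s2 <- summarize_train(event_train(tr2$event_times, tr2$duration))
  expect_equal(s2$skewness, 2, tolerance = 0.15)
})
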