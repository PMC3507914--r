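# Order-i inter-FP intervals, pooled cumulative probability curves,
# observation-duration quantiles, and per-train summaries.

#' Order-i inter-event intervals
#'
#' For event times t(1) < t(2) < ... < t(N), the order-i interval
#' starting at event n is I_i(n) = t(n+i) - t(n), defined for
#' 1 <= n <= N - i: the time within which the next i events occurred.
#' The open interval from the last event to the end of the recording is
#' censored and excluded, a known downward bias for the longest
#' intervals.
#'
#' @param train An [event_train()].
#' @param order Interval order i >= 1.
#' @return An object of class `fp_interval_set` with fields `order`,
#'   `intervals` (seconds, length `max(N - i, 0)`) and `muscle_id`.
#' @export
#' @examples
#' tr <- event_train(c(0, 10, 25, 27), recording_duration = 30)
#' compute_intervals(tr, 1)$intervals  # 10 15 2
#' compute_intervals(tr, 3)$intervals  # 27
compute_intervals <- function(train, order) {
  stopifnot(inherits(train, "fp_event_train"))
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be a positive integer")
  n <- length(train$times)
  ivals <- if (n > order) {
    train$times[(order + 1L):n] - train$times[1L:(n - order)]
  } else numeric(0)
  structure(
    list(order = order, intervals = ivals, muscle_id = train$muscle_id),
    class = "fp_interval_set"
  )
}

#' Pool interval sets and build the cumulative probability curve
#'
#' Pools order-i intervals and returns the empirical cumulative
#' distribution on a regular duration grid: the probability that i
#' events occur within an observation window of each duration. The
#' probability at duration T is right-continuous (`intervals <= T`
#' counted), so the curve reaches exactly 1 at the maximum pooled
#' interval, which the grid always includes as its last point.
#'
#' Two pooling modes: `"all_intervals"` pools every interval from every
#' muscle with equal weight (the whole-dataset distribution);
#' `"per_muscle_max"` pools only each muscle's maximum interval -- the
#' longest wait for i events seen in that muscle -- for sensitivity
#' analysis.
#'
#' @param interval_sets A single `fp_interval_set` or a list of them;
#'   sets whose order differs from `order` are rejected.
#' @param order Interval order i.
#' @param grid_step Grid resolution in seconds (default 1).
#' @param pooling `"all_intervals"` or `"per_muscle_max"`.
#' @return An object of class `fp_cum_curve` with fields `order`,
#'   `durations`, `probabilities`, `n_intervals`, `pooling`.
#' @export
pool_and_cumulate <- function(interval_sets, order, grid_step = 1,
                              pooling = c("all_intervals", "per_muscle_max")) {
  pooling <- match.arg(pooling)
  if (inherits(interval_sets, "fp_interval_set")) {
    interval_sets <- list(interval_sets)
  }
  stopifnot(length(interval_sets) >= 1L,
            all(vapply(interval_sets, inherits, logical(1), "fp_interval_set")),
            grid_step > 0)
  order <- as.integer(order)
  if (any(vapply(interval_sets, `[[`, integer(1), "order") != order)) {
    stop("interval sets must all have the requested order")
  }
  pooled <- switch(pooling,
    all_intervals = unlist(lapply(interval_sets, `[[`, "intervals")),
    per_muscle_max = {
      m <- vapply(interval_sets, function(s)
        if (length(s$intervals)) max(s$intervals) else NA_real_, numeric(1))
      m[!is.na(m)]
    }
  )
  if (!length(pooled)) stop(sprintf("no intervals at order %d", order))
  mx <- max(pooled)
  grid <- seq(0, mx, by = grid_step)
  if (grid[length(grid)] < mx) grid <- c(grid, mx)
  probs <- stats::ecdf(pooled)(grid)
  structure(
    list(order = order, durations = grid, probabilities = probs,
         n_intervals = length(pooled), pooling = pooling),
    class = "fp_cum_curve"
  )
}

#' @export
print.fp_cum_curve <- function(x, ...) {
  cat(sprintf("<fp_cum_curve> order %d, %d pooled intervals (%s), max %.1f s\n",
              x$order, x$n_intervals, x$pooling,
              x$durations[length(x$durations)]))
  invisible(x)
}

#' Observation duration needed to reach a detection probability
#'
#' The smallest grid duration at which the cumulative probability of
#' having observed i events reaches p. Because the curve is
#' right-continuous and its grid ends exactly at the maximum pooled
#' interval, `p = 1` returns that maximum.
#'
#' @param curve An `fp_cum_curve`.
#' @param p Target probability in (0, 1].
#' @return Duration in seconds.
#' @export
duration_for_probability <- function(curve, p) {
  stopifnot(inherits(curve, "fp_cum_curve"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("`p` must lie in (0, 1]")
  }
  curve$durations[which(curve$probabilities >= p)[1]]
}

#' Evaluate a cumulative curve at arbitrary durations
#'
#' Right-continuous step interpolation of the curve's grid values.
#'
#' @param curve An `fp_cum_curve`.
#' @param durations Durations in seconds.
#' @return Probabilities in `[0, 1]`.
#' @export
curve_probability <- function(curve, durations) {
  stats::approx(curve$durations, curve$probabilities, xout = durations,
                method = "constant", f = 0, yleft = 0, yright = 1)$y
}

#' Fisher--Pearson adjusted sample skewness
#'
#' `g1 * sqrt(n (n - 1)) / (n - 2)` where `g1` is the third
#' standardised sample moment. Returns 0 for zero-variance input
#' (perfectly regular intervals) and `NA` for fewer than 3 values.
#'
#' @param x Numeric vector.
#' @return Skewness (dimensionless).
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Summarise a fasciculation event train
#'
#' Event count, rate (events/minute), Fisher--Pearson adjusted skewness
#' of the order-1 intervals (reported as `NA` when fewer than 4 events,
#' i.e. fewer than 3 intervals), and the maximum interval per order.
#'
#' @param train An [event_train()].
#' @param max_order Highest interval order to summarise (default 5).
#' @return A one-row data frame: `muscle_id`, `n_events`,
#'   `rate_per_min`, `skewness`, `max_interval_i1` .. `max_interval_i<max_order>`.
#' @export
summarize_train <- function(train, max_order = 5L) {
  stopifnot(inherits(train, "fp_event_train"))
  n <- length(train$times)
  i1 <- compute_intervals(train, 1L)$intervals
  skew <- if (n >= 4L) sample_skewness(i1) else NA_real_
  maxima <- vapply(seq_len(max_order), function(i) {
    iv <- compute_intervals(train, i)$intervals
    if (length(iv)) max(iv) else NA_real_
  }, numeric(1))
  out <- data.frame(
    muscle_id = train$muscle_id, n_events = n,
    rate_per_min = n / train$recording_duration * 60,
    skewness = skew
  )
  out[sprintf("max_interval_i%d", seq_len(max_order))] <- as.list(maxima)
  out
}

#' Observation-duration table for a set of curves
#'
#' For each curve (interval order) and each target probability, the
#' observation duration required.
#'
#' @param curves List of `fp_cum_curve` objects.
#' @param probs Target probabilities in (0, 1].
#' @return Data frame with columns `order`, `p`, `duration_s`.
#' @export
duration_table <- function(curves, probs = c(0.5, 0.8, 0.9, 0.95, 0.99, 1.0)) {
  stopifnot(all(vapply(curves, inherits, logical(1), "fp_cum_curve")))
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(order = cv$order, p = probs,
               duration_s = vapply(probs, function(p)
                 duration_for_probability(cv, p), numeric(1)))
  }))
}
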