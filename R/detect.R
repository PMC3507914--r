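# Threshold-based spike detection across all channels with
# cross-channel consensus merging.

#' Detection configuration
#'
#' Parameters of the multi-channel threshold spike detector. The
#' threshold is noise-relative (a multiple of the per-channel robust
#' noise sigma), so detection is invariant to overall amplitude
#' scaling. Defaults follow standard extracellular spike-detection
#' practice: 5 x MAD-sigma threshold, 10 ms cross-channel coincidence
#' window, 20 ms refractory separation between distinct events, and a
#' consensus requirement of 3 channels on the 64-channel grid (2 on the
#' 20-channel linear array, where a source can sit near the array end).
#'
#' @param band Band-pass edges in Hz, applied with zero-phase
#'   (forward-backward) filtering so detection times are not
#'   phase-shifted; the default re-applies the 20--500 Hz acquisition
#'   band.
#' @param threshold_k Threshold as a multiple of the MAD-based noise
#'   sigma (> 0).
#' @param merge_window_ms Cross-channel coincidence window, ms (> 0).
#' @param min_channels Minimum number of channels that must detect a
#'   spike for it to count as an FP event (artifact rejection).
#' @param refractory_ms Minimum separation of distinct events, ms; must
#'   be at least `merge_window_ms`.
#' @param polarity `"both"`, `"positive"` or `"negative"` excursions.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(band = c(20, 500), threshold_k = 5,
                             merge_window_ms = 10, min_channels = 3,
                             refractory_ms = 20,
                             polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            threshold_k > 0, merge_window_ms > 0, min_channels >= 1)
  if (refractory_ms < merge_window_ms) {
    stop("`refractory_ms` must be at least `merge_window_ms`")
  }
  structure(
    list(band = as.numeric(band), threshold_k = threshold_k,
         merge_window_ms = merge_window_ms,
         min_channels = as.integer(min_channels),
         refractory_ms = refractory_ms, polarity = polarity),
    class = "detection_config"
  )
}

#' Robust per-channel noise level
#'
#' Median-absolute-deviation estimate of the noise standard deviation,
#' `MAD / 0.6745`, which is insensitive to sparse large spikes riding
#' on the baseline (unlike the plain standard deviation, which a few
#' high-amplitude events inflate badly).
#'
#' @param channel_signal Numeric vector of samples.
#' @return Noise sigma in the signal's units; an all-constant channel
#'   returns 0 with a warning (effectively dead).
#' @export
estimate_noise_level <- function(channel_signal) {
  stopifnot(is.numeric(channel_signal), length(channel_signal) >= 1L)
  sigma <- stats::mad(channel_signal)  # 1.4826 * MAD = MAD / 0.6745
  if (sigma == 0) {
    warning("constant channel: noise level 0 (channel effectively dead)")
  }
  sigma
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so filtering adds no group delay and event
#' times are preserved.
#'
#' @param x Numeric sample vector.
#' @param sample_rate Sampling rate, Hz.
#' @param band `c(low, high)` in Hz; `high` must be below Nyquist.
#' @return Filtered vector.
#' @export
bandpass_filter <- function(x, sample_rate, band = c(20, 500)) {
  if (band[2] >= sample_rate / 2) {
    stop("upper band edge must be below the Nyquist frequency")
  }
  bf <- signal::butter(4, band / (sample_rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Detect spikes on a single channel
#'
#' Marks supra-threshold excursions of the (already band-passed)
#' signal and returns, for each excursion, the time of its absolute
#' peak; excursions closer than the refractory period are merged,
#' keeping the larger peak.
#'
#' @param channel_signal Band-pass filtered samples.
#' @param sample_rate Sampling rate, Hz.
#' @param config A [detection_config()].
#' @param noise_sigma Optional precomputed noise level; estimated with
#'   [estimate_noise_level()] when `NULL`.
#' @return A data frame with columns `time` (s) and `peak` (absolute
#'   peak amplitude); zero rows when nothing crosses threshold.
#' @export
detect_channel_spikes <- function(channel_signal, sample_rate, config,
                                  noise_sigma = NULL) {
  stopifnot(inherits(config, "detection_config"))
  if (config$band[2] >= sample_rate / 2) {
    stop("upper band edge must be below the Nyquist frequency")
  }
  if (is.null(noise_sigma)) {
    noise_sigma <- suppressWarnings(estimate_noise_level(channel_signal))
  }
  empty <- data.frame(time = numeric(0), peak = numeric(0))
  if (noise_sigma <= 0) return(empty)
  s <- switch(config$polarity,
    both = abs(channel_signal),
    positive = channel_signal,
    negative = -channel_signal
  )
  thr <- config$threshold_k * noise_sigma
  above <- s > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  peak_idx <- mapply(function(a, b) a - 1L + which.max(s[a:b]), starts, ends)
  peaks <- s[peak_idx]
  # refractory: sweep in time, merge excursions closer than refractory
  refr <- config$refractory_ms / 1000 * sample_rate
  keep_idx <- integer(0); keep_peak <- numeric(0)
  for (j in seq_along(peak_idx)) {
    k <- length(keep_idx)
    if (k && (peak_idx[j] - keep_idx[k]) < refr) {
      if (peaks[j] > keep_peak[k]) {
        keep_idx[k] <- peak_idx[j]; keep_peak[k] <- peaks[j]
      }
    } else {
      keep_idx <- c(keep_idx, peak_idx[j])
      keep_peak <- c(keep_peak, peaks[j])
    }
  }
  data.frame(time = (keep_idx - 1L) / sample_rate, peak = keep_peak)
}

#' Merge per-channel detections into FP events
#'
#' Pools detections from all channels, clusters those within the
#' coincidence window (single linkage on consecutive sorted times),
#' assigns each cluster the time of its globally largest per-channel
#' peak (robust to low-amplitude channels), discards clusters supported
#' by fewer than `min_channels` distinct channels, and finally merges
#' surviving events closer than the refractory period so the output is
#' strictly increasing with gaps of at least the refractory.
#'
#' @param per_channel_detections List of data frames as returned by
#'   [detect_channel_spikes()], one per channel; names or list position
#'   identify the channel.
#' @param config A [detection_config()].
#' @return A data frame of FP events: `time` (s), `n_channels`,
#'   `peak_uv`, and a list column `channels_hit`.
#' @export
merge_detections <- function(per_channel_detections, config) {
  stopifnot(inherits(config, "detection_config"))
  chans <- names(per_channel_detections)
  if (is.null(chans)) chans <- as.character(seq_along(per_channel_detections))
  rows <- lapply(seq_along(per_channel_detections), function(i) {
    d <- per_channel_detections[[i]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    data.frame(time = d$time, peak = d$peak, channel = as.integer(chans[i]))
  })
  all <- do.call(rbind, rows)
  empty <- data.frame(time = numeric(0), n_channels = integer(0),
                      peak_uv = numeric(0))
  empty$channels_hit <- list()
  if (is.null(all) || nrow(all) == 0L) return(empty)
  all <- all[order(all$time), , drop = FALSE]
  win <- config$merge_window_ms / 1000
  cluster <- cumsum(c(TRUE, diff(all$time) > win))
  ev <- lapply(split(all, cluster), function(g) {
    top <- which.max(g$peak)
    list(time = g$time[top], peak = g$peak[top],
         channels = sort(unique(g$channel)))
  })
  ev <- Filter(function(e) length(e$channels) >= config$min_channels, ev)
  if (!length(ev)) return(empty)
  # refractory pass over consensus times
  refr <- config$refractory_ms / 1000
  merged <- list(ev[[1]])
  for (e in ev[-1]) {
    last <- merged[[length(merged)]]
    if (e$time - last$time < refr) {
      keep <- if (e$peak > last$peak) e else last
      keep$channels <- sort(unique(c(last$channels, e$channels)))
      merged[[length(merged)]] <- keep
    } else {
      merged[[length(merged) + 1L]] <- e
    }
  }
  out <- data.frame(
    time = vapply(merged, `[[`, numeric(1), "time"),
    n_channels = vapply(merged, function(e) length(e$channels), integer(1)),
    peak_uv = vapply(merged, `[[`, numeric(1), "peak")
  )
  out$channels_hit <- lapply(merged, `[[`, "channels")
  out
}

#' Detect fasciculation potentials in a recording
#'
#' Full detector: excludes dead channels (those flagged in the live
#' mask, plus any whose noise estimate is 0 or more than 10 x the
#' median channel noise, mirroring the practice of disconnecting
#' poor-quality electrodes), zero-phase band-pass filters each live
#' channel, runs per-channel threshold detection, and merges detections
#' across channels into consensus FP events.
#'
#' @param recording An [hdsemg_recording()].
#' @param config A [detection_config()]; linear arrays may warrant
#'   `min_channels = 2`.
#' @return An [event_train()] of FP occurrence times, with the event
#'   table attached as attribute `"events"` and the channels used as
#'   attribute `"channels_used"`.
#' @export
detect <- function(recording, config = detection_config()) {
  stopifnot(inherits(recording, "hdsemg_recording"),
            inherits(config, "detection_config"))
  fs <- recording$sample_rate
  live <- which(recording$live_mask)
  if (!length(live)) stop("no live channels")
  filtered <- lapply(live, function(ch)
    bandpass_filter(recording$signal[ch, ], fs, config$band))
  sigma <- vapply(filtered, function(x)
    suppressWarnings(estimate_noise_level(x)), numeric(1))
  # An effectively noiseless channel (negligible MAD relative to its
  # peak, e.g. sparse spikes on a silent baseline) gets a fallback
  # threshold of half its absolute maximum; a channel that is zero-MAD
  # and silent is dead.
  ch_max <- vapply(filtered, function(x) max(abs(x)), numeric(1))
  noisefree <- ch_max > 0 & sigma < ch_max * 1e-6
  sigma[noisefree] <- ch_max[noisefree] / (2 * config$threshold_k)
  med <- stats::median(sigma[sigma > 0])
  good <- sigma > 0 & sigma <= 10 * med
  if (!any(good)) stop("no live channels")
  live <- live[good]
  filtered <- filtered[good]
  sigma <- sigma[good]
  per_channel <- lapply(seq_along(live), function(i)
    detect_channel_spikes(filtered[[i]], fs, config, noise_sigma = sigma[i]))
  names(per_channel) <- as.character(live)
  events <- merge_detections(per_channel, config)
  tr <- event_train(events$time, recording$duration,
                    muscle_id = recording$muscle_id)
  attr(tr, "events") <- events
  attr(tr, "channels_used") <- live
  tr
}

#' Match detected event times against ground truth
#'
#' Greedy one-to-one matching: each truth event is paired with the
#' nearest unused detection within the tolerance.
#'
#' @param detected Numeric vector of detected times (s).
#' @param truth Numeric vector of true times (s).
#' @param tol_s Matching tolerance in seconds (default 5 ms).
#' @return A list with counts `tp`, `fp`, `fn` and scores `precision`,
#'   `recall`, `f1`.
#' @export
match_event_times <- function(detected, truth, tol_s = 0.005) {
  used <- rep.int(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(c(d, Inf))
    if (j <= length(detected) && d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}
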