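# Renewal-process event trains and synthetic multi-channel HD-SEMG recordings.

#' Renewal-process specification for fasciculation timing
#'
#' Describes the inter-event interval distribution of a simulated
#' fasciculating motor unit. Intervals are independent and identically
#' distributed (a renewal process), which is the simplest point-process
#' model consistent with summarising spontaneous activity purely by its
#' interval distribution. A gamma distribution with shape around 3--4
#' yields interval skewness near 1, the magnitude reported for inter-FP
#' intervals in ALS muscles; the exponential (Poisson process) special
#' case has closed-form order-i interval distributions used as test
#' oracles.
#'
#' @param distribution One of `"exponential"`, `"gamma"`, `"lognormal"`.
#' @param mean_rate Mean event rate in events per minute (> 0).
#' @param shape Gamma shape parameter or lognormal sigma (> 0); ignored
#'   for `"exponential"`. Theoretical interval skewness is 2 for the
#'   exponential and `2/sqrt(shape)` for the gamma.
#' @param seed Integer seed fixing the train, or `NULL` to use the
#'   current RNG state.
#' @return An object of class `renewal_spec`.
#' @export
#' @examples
#' sp <- renewal_spec("gamma", mean_rate = 12, shape = 3.5, seed = 1)
#' tr <- generate_event_train(sp, duration = 600)
#' length(tr$event_times)
renewal_spec <- function(distribution = c("exponential", "gamma", "lognormal"),
                         mean_rate, shape = 1, seed = NULL) {
  distribution <- match.arg(distribution)
  if (!is.numeric(mean_rate) || length(mean_rate) != 1L || !is.finite(mean_rate) ||
      mean_rate <= 0) {
    stop("`mean_rate` must be a single positive number (events/minute)")
  }
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0) {
    stop("`shape` must be a single positive number")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(distribution = distribution, mean_rate = mean_rate,
         shape = shape, seed = seed),
    class = "renewal_spec"
  )
}

#' Theoretical skewness of a renewal spec's interval distribution
#'
#' Closed forms: 2 for exponential intervals, `2/sqrt(shape)` for gamma,
#' `(exp(s^2) + 2) * sqrt(exp(s^2) - 1)` for lognormal with sigma `s`.
#'
#' @param spec A [renewal_spec()].
#' @return Skewness (dimensionless).
#' @export
theoretical_skewness <- function(spec) {
  stopifnot(inherits(spec, "renewal_spec"))
  switch(spec$distribution,
    exponential = 2,
    gamma = 2 / sqrt(spec$shape),
    lognormal = {
      w <- exp(spec$shape^2)
      (w + 2) * sqrt(w - 1)
    }
  )
}

draw_intervals <- function(spec, n) {
  mu <- 60 / spec$mean_rate  # mean inter-event interval, seconds
  switch(spec$distribution,
    exponential = stats::rexp(n, rate = 1 / mu),
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$shape / mu),
    lognormal = stats::rlnorm(n, meanlog = log(mu) - spec$shape^2 / 2,
                              sdlog = spec$shape)
  )
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth fasciculation event train
#'
#' Draws i.i.d. inter-event intervals from the spec's distribution and
#' accumulates them from time 0 until the recording duration is
#' exceeded. Event times are strictly increasing and lie in
#' `[0, duration]`; the expected count is `mean_rate * duration / 60`.
#'
#' @param spec A [renewal_spec()].
#' @param duration Recording duration in seconds (> 0).
#' @param source_id Integer label attached to every event (which
#'   simulated motor unit produced it).
#' @return An object of class `fp_ground_truth` with fields
#'   `event_times` (seconds), `source_ids`, and `duration`.
#' @export
generate_event_train <- function(spec, duration, source_id = 1L) {
  stopifnot(inherits(spec, "renewal_spec"))
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number of seconds")
  }
  times <- with_seed(spec$seed, {
    expected <- spec$mean_rate * duration / 60
    block <- max(16L, ceiling(expected + 6 * sqrt(expected + 1)))
    tt <- cumsum(draw_intervals(spec, block))
    while (tt[length(tt)] <= duration) {
      tt <- c(tt, tt[length(tt)] + cumsum(draw_intervals(spec, block)))
    }
    tt[tt <= duration]
  })
  ground_truth(times, rep.int(as.integer(source_id), length(times)), duration)
}

#' Construct a ground-truth event set
#'
#' @param event_times Strictly increasing event times in seconds.
#' @param source_ids Integer source label per event.
#' @param duration Recording duration in seconds.
#' @return An object of class `fp_ground_truth`.
#' @export
ground_truth <- function(event_times, source_ids = rep.int(1L, length(event_times)),
                         duration) {
  event_times <- as.numeric(event_times)
  if (length(event_times) && (any(event_times < 0) || any(event_times > duration))) {
    stop("event times must lie within [0, duration]")
  }
  if (length(event_times) > 1L && any(diff(event_times) <= 0)) {
    stop("event times must be strictly increasing")
  }
  if (length(source_ids) != length(event_times)) {
    stop("`source_ids` must have one label per event")
  }
  structure(
    list(event_times = event_times, source_ids = as.integer(source_ids),
         duration = as.numeric(duration)),
    class = "fp_ground_truth"
  )
}

#' Merge ground-truth trains from several motor units
#'
#' Events from different sources closer together than `coincidence_s`
#' are merged into a single event (keeping the earlier time and its
#' source label): the analysis counts fasciculation potentials
#' regardless of waveform or unit of origin, so near-simultaneous
#' discharges are indistinguishable from one event.
#'
#' @param ... `fp_ground_truth` objects with equal durations.
#' @param coincidence_s Merge window in seconds (default 1 ms).
#' @return A merged `fp_ground_truth`.
#' @export
merge_ground_truth <- function(..., coincidence_s = 0.001) {
  truths <- list(...)
  stopifnot(length(truths) >= 1L,
            all(vapply(truths, inherits, logical(1), "fp_ground_truth")))
  dur <- unique(vapply(truths, function(t) t$duration, numeric(1)))
  if (length(dur) != 1L) stop("all trains must share the same duration")
  times <- unlist(lapply(truths, `[[`, "event_times"))
  src <- unlist(lapply(truths, `[[`, "source_ids"))
  ord <- order(times)
  times <- times[ord]; src <- src[ord]
  keep <- if (length(times)) c(TRUE, diff(times) >= coincidence_s) else logical(0)
  ground_truth(times[keep], src[keep], dur)
}

#' Electrode-array geometry
#'
#' The two arrays used for surface FP recording: a flexible 8 x 8 grid
#' of 64 electrodes with 4 mm inter-electrode distance (intrinsic hand
#' muscles), and a 20-channel linear bar array with 5 mm pitch (biceps
#' brachii). Channel labels encode position (`"G-r3c5"`, `"L-07"`).
#'
#' @param layout `"grid"` or `"linear"`.
#' @param n_channels Channel count; defaults to 64 (grid) or 20 (linear).
#'   Grid counts must be perfect squares.
#' @param pitch_mm Inter-electrode distance in mm; defaults 4 (grid),
#'   5 (linear).
#' @return An object of class `array_geometry` with `channel_positions`
#'   (n x 2 matrix, mm) and `labels`.
#' @export
array_geometry <- function(layout = c("grid", "linear"), n_channels = NULL,
                           pitch_mm = NULL) {
  layout <- match.arg(layout)
  if (layout == "grid") {
    if (is.null(n_channels)) n_channels <- 64L
    if (is.null(pitch_mm)) pitch_mm <- 4
    side <- sqrt(n_channels)
    if (side != round(side)) stop("grid layout requires a square channel count")
    side <- as.integer(side)
    rc <- expand.grid(col = seq_len(side), row = seq_len(side))
    pos <- cbind(x = (rc$col - 1L) * pitch_mm, y = (rc$row - 1L) * pitch_mm)
    labels <- sprintf("G-r%dc%d", rc$row, rc$col)
  } else {
    if (is.null(n_channels)) n_channels <- 20L
    if (is.null(pitch_mm)) pitch_mm <- 5
    pos <- cbind(x = (seq_len(n_channels) - 1L) * pitch_mm, y = 0)
    labels <- sprintf("L-%02d", seq_len(n_channels))
  }
  if (anyDuplicated(pos)) stop("channel positions must be pairwise distinct")
  structure(
    list(layout = layout, n_channels = as.integer(n_channels),
         pitch_mm = pitch_mm, channel_positions = pos, labels = labels),
    class = "array_geometry"
  )
}

#' Fasciculation-potential waveform model
#'
#' Multi-channel template for one surface-recorded FP: a temporal kernel
#' (default the first derivative of a Gaussian -- a biphasic spike with
#' 10 ms support, typical of surface-recorded motor unit discharges)
#' scaled per channel by a spatial attenuation profile decaying with
#' distance from the source position. The attenuation profile is
#' normalised so the closest channel carries the nominal amplitude.
#'
#' @param duration_ms Kernel support in ms.
#' @param amplitude_uv Nominal peak amplitude in microvolts on the peak
#'   channel. Surface FP amplitudes for these muscles are not well
#'   characterised; the default (150 uV) is a mid-range choice and fully
#'   configurable.
#' @param decay `"exponential"` or `"gaussian"` spatial decay.
#' @param length_constant_mm Decay length constant in mm.
#' @param jitter_sd_ms Per-channel latency jitter standard deviation, ms.
#' @return An object of class `fp_waveform`.
#' @export
fp_waveform <- function(duration_ms = 10, amplitude_uv = 150,
                        decay = c("exponential", "gaussian"),
                        length_constant_mm = 10, jitter_sd_ms = 0.2) {
  decay <- match.arg(decay)
  stopifnot(duration_ms > 0, amplitude_uv > 0, length_constant_mm > 0,
            jitter_sd_ms >= 0)
  structure(
    list(duration_ms = duration_ms, amplitude_uv = amplitude_uv,
         decay = decay, length_constant_mm = length_constant_mm,
         jitter_sd_ms = jitter_sd_ms),
    class = "fp_waveform"
  )
}

# Biphasic temporal kernel sampled at `sample_rate`, peak |value| = amplitude.
waveform_kernel <- function(waveform, sample_rate) {
  half <- waveform$duration_ms / 2000  # seconds
  tt <- seq(-half, half, by = 1 / sample_rate)
  sig <- half / 3  # +-3 sd inside the support
  k <- -tt * exp(-tt^2 / (2 * sig^2))
  k / max(abs(k)) * waveform$amplitude_uv
}

# Per-channel attenuation from a source at (x, y) mm, max normalised to 1.
spatial_attenuation <- function(waveform, geometry, source_xy) {
  d <- sqrt((geometry$channel_positions[, 1] - source_xy[1])^2 +
            (geometry$channel_positions[, 2] - source_xy[2])^2)
  a <- switch(waveform$decay,
    exponential = exp(-d / waveform$length_constant_mm),
    gaussian = exp(-d^2 / (2 * waveform$length_constant_mm^2))
  )
  a / max(a)
}

#' Synthesize a multi-channel HD-SEMG recording from ground truth
#'
#' Places a spatially attenuated copy of the waveform kernel at every
#' event time on each live channel, optionally with per-channel latency
#' jitter, and adds band-limited (20--500 Hz by default, the acquisition
#' system band) Gaussian noise scaled to an exact per-channel RMS.
#' Dead channels are flatlined and flagged in the live mask, emulating
#' electrodes disconnected for poor contact (typically 2--5 per
#' experiment).
#'
#' @param truth An `fp_ground_truth`.
#' @param geometry An [array_geometry()].
#' @param waveform An [fp_waveform()].
#' @param noise_rms Per-channel noise RMS in microvolts (0 for noise-free).
#' @param sample_rate Sampling rate in Hz (default 2000).
#' @param dead_channels Integer indices of disconnected channels.
#' @param band Noise band in Hz, `c(low, high)`; `high` must be below
#'   the Nyquist frequency.
#' @param source_positions Optional matrix of (x, y) mm rows indexed by
#'   source id; drawn uniformly over the array footprint when `NULL`.
#' @param seed Integer seed for noise, jitter and source placement, or
#'   `NULL`.
#' @param muscle_id Identifier stored on the recording.
#' @return An [hdsemg_recording()].
#' @export
synthesize_recording <- function(truth, geometry, waveform = fp_waveform(),
                                 noise_rms = 10, sample_rate = 2000,
                                 dead_channels = integer(0),
                                 band = c(20, 500),
                                 source_positions = NULL, seed = NULL,
                                 muscle_id = "synthetic") {
  stopifnot(inherits(truth, "fp_ground_truth"),
            inherits(geometry, "array_geometry"),
            inherits(waveform, "fp_waveform"))
  if (sample_rate < 2 * band[2]) {
    stop("sample_rate must be at least twice the upper band edge")
  }
  if (length(dead_channels) &&
      (any(dead_channels < 1L) || any(dead_channels > geometry$n_channels))) {
    stop("`dead_channels` must be valid channel indices")
  }
  n_samples <- round(truth$duration * sample_rate)
  kernel <- waveform_kernel(waveform, sample_rate)
  if (length(kernel) > n_samples) stop("waveform longer than the recording")
  if (length(truth$event_times) && any(truth$event_times > truth$duration)) {
    stop("event time beyond recording duration")
  }
  n_ch <- geometry$n_channels

  sig <- with_seed(seed, {
    src_ids <- sort(unique(truth$source_ids))
    if (is.null(source_positions)) {
      lo <- apply(geometry$channel_positions, 2, min)
      hi <- apply(geometry$channel_positions, 2, max)
      source_positions <- cbind(stats::runif(max(src_ids, 1L), lo[1], hi[1]),
                                stats::runif(max(src_ids, 1L), lo[2], hi[2]))
    }
    atten <- lapply(src_ids, function(s)
      spatial_attenuation(waveform, geometry, source_positions[s, ]))
    names(atten) <- as.character(src_ids)

    x <- matrix(0, nrow = n_ch, ncol = n_samples)
    half_len <- (length(kernel) - 1L) %/% 2L
    jit_sd <- waveform$jitter_sd_ms / 1000
    for (e in seq_along(truth$event_times)) {
      centre <- round(truth$event_times[e] * sample_rate) + 1L
      a <- atten[[as.character(truth$source_ids[e])]]
      shifts <- if (jit_sd > 0) {
        as.integer(round(stats::rnorm(n_ch, 0, jit_sd) * sample_rate))
      } else integer(n_ch)
      for (ch in seq_len(n_ch)) {
        i0 <- centre + shifts[ch] - half_len
        idx <- seq.int(i0, i0 + length(kernel) - 1L)
        ok <- idx >= 1L & idx <= n_samples
        if (any(ok)) x[ch, idx[ok]] <- x[ch, idx[ok]] + a[ch] * kernel[ok]
      }
    }
    if (noise_rms > 0) {
      bf <- signal::butter(4, band / (sample_rate / 2), type = "pass")
      for (ch in seq_len(n_ch)) {
        nz <- signal::filtfilt(bf, stats::rnorm(n_samples))
        x[ch, ] <- x[ch, ] + nz * (noise_rms / sqrt(mean(nz^2)))
      }
    }
    x
  })

  live <- rep.int(TRUE, n_ch)
  if (length(dead_channels)) {
    live[dead_channels] <- FALSE
    sig[dead_channels, ] <- 0
  }
  hdsemg_recording(sig, sample_rate, geometry, live_mask = live,
                   muscle_id = muscle_id)
}
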