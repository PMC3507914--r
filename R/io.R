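# Containers and file formats: native float32 binary + JSON sidecar,
# EDF, and event-train CSV.

#' Multi-channel HD-SEMG recording container
#'
#' @param signal Numeric matrix, `n_channels x n_samples`, microvolts.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param geometry An [array_geometry()] matching the channel count.
#' @param live_mask Logical vector, one entry per channel; at least one
#'   channel must be live.
#' @param muscle_id Identifier string.
#' @return An object of class `hdsemg_recording`; `duration` is derived
#'   as `n_samples / sample_rate`.
#' @export
hdsemg_recording <- function(signal, sample_rate, geometry,
                             live_mask = rep.int(TRUE, nrow(signal)),
                             muscle_id = "unknown") {
  stopifnot(is.matrix(signal), is.numeric(signal),
            inherits(geometry, "array_geometry"))
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  if (nrow(signal) != geometry$n_channels) {
    stop(sprintf("signal has %d channels but geometry declares %d",
                 nrow(signal), geometry$n_channels))
  }
  if (length(live_mask) != nrow(signal)) {
    stop("`live_mask` must have one entry per channel")
  }
  if (!any(live_mask)) stop("no live channels")
  structure(
    list(signal = signal, sample_rate = sample_rate, geometry = geometry,
         live_mask = as.logical(live_mask),
         duration = ncol(signal) / sample_rate,
         muscle_id = muscle_id),
    class = "hdsemg_recording"
  )
}

#' @export
print.hdsemg_recording <- function(x, ...) {
  cat(sprintf("<hdsemg_recording> %s: %d channels (%d live), %.1f s @ %g Hz, %s array\n",
              x$muscle_id, nrow(x$signal), sum(x$live_mask), x$duration,
              x$sample_rate, x$geometry$layout))
  invisible(x)
}

#' Fasciculation event train
#'
#' Occurrence times of detected (or simulated) fasciculation potentials
#' in one muscle, with the recording duration needed to express rates
#' and censoring.
#'
#' @param times Strictly increasing event times in seconds, all within
#'   `[0, recording_duration]`.
#' @param recording_duration Recording length in seconds.
#' @param muscle_id Identifier string.
#' @return An object of class `fp_event_train`.
#' @export
event_train <- function(times, recording_duration, muscle_id = "unknown") {
  times <- as.numeric(times)
  if (!is.numeric(recording_duration) || recording_duration <= 0) {
    stop("`recording_duration` must be positive")
  }
  if (length(times)) {
    if (any(times < 0) || any(times > recording_duration)) {
      stop("event times must lie within [0, recording_duration]")
    }
    if (length(times) > 1L && any(diff(times) <= 0)) {
      stop("event times must be strictly increasing")
    }
  }
  structure(
    list(muscle_id = muscle_id, times = times,
         recording_duration = as.numeric(recording_duration)),
    class = "fp_event_train"
  )
}

#' @export
print.fp_event_train <- function(x, ...) {
  cat(sprintf("<fp_event_train> %s: N = %d over %.1f s (%.2f /min)\n",
              x$muscle_id, length(x$times), x$recording_duration,
              length(x$times) / x$recording_duration * 60))
  invisible(x)
}

geometry_to_list <- function(geometry) {
  list(layout = geometry$layout, n_channels = geometry$n_channels,
       pitch_mm = geometry$pitch_mm,
       channel_positions = unname(geometry$channel_positions),
       labels = geometry$labels)
}

geometry_from_list <- function(g) {
  geo <- array_geometry(g$layout, n_channels = g$n_channels,
                        pitch_mm = g$pitch_mm)
  pos <- matrix(unlist(g$channel_positions), ncol = 2, byrow = !is.matrix(g$channel_positions))
  if (is.matrix(g$channel_positions)) pos <- g$channel_positions
  if (nrow(pos) != geo$n_channels) {
    stop("sidecar geometry has a channel-position count inconsistent with n_channels")
  }
  geo
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a recording
#'
#' Two containers are supported, selected by the file extension:
#' `.bin` -- the native lossless layout, little-endian float32 samples
#' (channel-major) plus a JSON sidecar holding sample rate, geometry,
#' live mask and sample count; `.edf` -- standard European Data Format
#' (16-bit), with the same JSON sidecar carrying the geometry and exact
#' duration (EDF pads the final data record to a whole second).
#'
#' @param recording An [hdsemg_recording()].
#' @param path Output path ending in `.bin` or `.edf`; the sidecar is
#'   written next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "hdsemg_recording"))
  ext <- tolower(tools::file_ext(path))
  meta <- list(
    format = if (ext == "edf") "edf+sidecar" else "float32le+sidecar",
    muscle_id = recording$muscle_id,
    sample_rate = recording$sample_rate,
    n_channels = nrow(recording$signal),
    n_samples = ncol(recording$signal),
    duration_s = recording$duration,
    live_mask = recording$live_mask,
    geometry = geometry_to_list(recording$geometry)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (ext == "edf") {
    write_edf(recording, path)
  } else if (ext == "bin") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(recording$signal)), con, size = 4L,
             endian = "little")
  } else {
    stop("unsupported recording extension: use .bin or .edf")
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' The native float32 layout round-trips bit-exactly (values are stored
#' as float32); EDF round-trips exactly to its 16-bit quantization step.
#' A missing or inconsistent JSON sidecar is an error, never silently
#' ignored.
#'
#' @param path Path to a `.bin` or `.edf` file with its `.json` sidecar.
#' @return An [hdsemg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing geometry sidecar: expected ", sc)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  geometry <- geometry_from_list(meta$geometry)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    sig <- read_edf_signal(path)
    if (nrow(sig) != meta$n_channels) {
      stop(sprintf("EDF holds %d channels but sidecar declares %d",
                   nrow(sig), meta$n_channels))
    }
    sig <- sig[, seq_len(meta$n_samples), drop = FALSE]  # drop record padding
  } else {
    n <- meta$n_channels * meta$n_samples
    con <- file(path, "rb")
    on.exit(close(con))
    raw <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
    if (length(raw) != n) stop("binary payload shorter than sidecar declares")
    sig <- matrix(raw, nrow = meta$n_channels, byrow = TRUE)
  }
  hdsemg_recording(sig, meta$sample_rate, geometry,
                   live_mask = meta$live_mask, muscle_id = meta$muscle_id)
}

#' Write an event train as CSV
#'
#' Plain CSV with header `time_s[,source_id]`, preceded by comment lines
#' recording the muscle id and the recording duration. Times are stored
#' with 6 decimal places (1 microsecond), far below the 0.5 ms sample
#' period of a 2 kHz acquisition.
#'
#' @param train An [event_train()].
#' @param path Output CSV path.
#' @param source_ids Optional integer labels, one per event.
#' @return `path`, invisibly.
#' @export
write_event_train <- function(train, path, source_ids = NULL) {
  stopifnot(inherits(train, "fp_event_train"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# muscle_id: %s", train$muscle_id),
    sprintf("# recording_duration_s: %.6f", train$recording_duration)
  ), con)
  if (is.null(source_ids)) {
    writeLines("time_s", con)
    if (length(train$times)) {
      writeLines(sprintf("%.6f", train$times), con)
    }
  } else {
    stopifnot(length(source_ids) == length(train$times))
    writeLines("time_s,source_id", con)
    if (length(train$times)) {
      writeLines(sprintf("%.6f,%d", train$times, as.integer(source_ids)), con)
    }
  }
  invisible(path)
}

#' Read an event train CSV
#'
#' Accepts files written by [write_event_train()] and any CSV with a
#' `time_s` column; the recording duration is taken from the
#' `# recording_duration_s:` header comment or, failing that, from the
#' `recording_duration` argument. Unsorted or negative times are
#' rejected.
#'
#' @param path CSV path.
#' @param recording_duration Fallback duration in seconds when the file
#'   carries none.
#' @return An [event_train()]; detected `source_id` columns are attached
#'   as attribute `"source_ids"`.
#' @export
read_event_train <- function(path, recording_duration = NULL) {
  if (!file.exists(path)) stop("event file not found: ", path)
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  muscle_id <- sub("^# *muscle_id: *", "",
                   grep("^# *muscle_id:", comments, value = TRUE)[1])
  dur_line <- grep("^# *recording_duration_s:", comments, value = TRUE)
  if (length(dur_line)) {
    recording_duration <- as.numeric(sub("^# *recording_duration_s: *", "",
                                         dur_line[1]))
  }
  if (is.null(recording_duration) || is.na(recording_duration)) {
    stop("recording duration missing: not in a header comment and not supplied")
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!"time_s" %in% names(df)) stop("CSV must have a `time_s` column")
  if (is.na(muscle_id)) muscle_id <- "unknown"
  tr <- event_train(df$time_s, recording_duration, muscle_id = muscle_id)
  if ("source_id" %in% names(df)) {
    attr(tr, "source_ids") <- as.integer(df$source_id)
  }
  tr
}
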