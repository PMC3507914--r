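# Minimal EDF (European Data Format) writer/reader: ASCII header plus
# 16-bit little-endian samples in fixed-duration data records. Covers
# plain continuous EDF only (no annotations, no EDF+ discontinuities),
# which is all a resting HD-SEMG recording needs. Physical calibration
# is per channel; quantization error is bounded by half the physical
# range divided by 2^15.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1L, width = 1L)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  pad_field(s, width)
}

# One data record per second; the final partial record is zero-padded.
write_edf <- function(recording, path) {
  sig <- recording$signal
  n_ch <- nrow(sig)
  fs <- recording$sample_rate
  if (fs != round(fs)) stop("EDF export requires an integer sample rate")
  spr <- as.integer(fs)              # samples per record per channel
  n_rec <- as.integer(ceiling(ncol(sig) / spr))

  phys_max <- max(1e-6, max(abs(sig)))
  phys_min <- -phys_max
  dig_max <- 32767L
  dig_min <- -32767L
  scale <- (dig_max - dig_min) / (phys_max - phys_min)

  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    pad_field("0", 8L),
    pad_field(recording$muscle_id, 80L),
    pad_field("fpwatch synthetic HD-SEMG", 80L),
    pad_field("01.01.00", 8L),
    pad_field("00.00.00", 8L),
    pad_field(as.character(256L * (1L + n_ch)), 8L),
    pad_field("", 44L),
    pad_field(as.character(n_rec), 8L),
    pad_field("1", 8L),
    pad_field(as.character(n_ch), 4L)
  )
  labels <- recording$geometry$labels
  header <- paste0(
    header,
    paste(vapply(labels, pad_field, character(1), width = 16L), collapse = ""),
    strrep(pad_field("surface electrode", 80L), n_ch),
    strrep(pad_field("uV", 8L), n_ch),
    strrep(edf_num(phys_min, 8L), n_ch),
    strrep(edf_num(phys_max, 8L), n_ch),
    strrep(pad_field(dig_min, 8L), n_ch),
    strrep(pad_field(dig_max, 8L), n_ch),
    strrep(pad_field("BP:20-500Hz", 80L), n_ch),
    strrep(pad_field(spr, 8L), n_ch),
    strrep(pad_field("", 32L), n_ch)
  )
  writeChar(header, con, eos = NULL)

  total <- n_rec * spr
  padded <- matrix(0, nrow = n_ch, ncol = total)
  padded[, seq_len(ncol(sig))] <- sig
  dig <- round((padded - phys_min) * scale) + dig_min
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  fixed <- readChar(con, 256L, useBytes = TRUE)
  n_ch <- as.integer(substr(fixed, 253L, 256L))
  n_rec <- as.integer(substr(fixed, 237L, 244L))
  rec_dur <- as.numeric(substr(fixed, 245L, 252L))
  per <- function(width) {
    raw <- readChar(con, width * n_ch, useBytes = TRUE)
    trimws(substring(raw, (seq_len(n_ch) - 1L) * width + 1L,
                     seq_len(n_ch) * width))
  }
  labels <- per(16L); per(80L); per(8L)
  phys_min <- as.numeric(per(8L)); phys_max <- as.numeric(per(8L))
  dig_min <- as.numeric(per(8L)); dig_max <- as.numeric(per(8L))
  per(80L)
  spr <- as.integer(per(8L)); per(32L)
  list(n_ch = n_ch, n_rec = n_rec, rec_dur = rec_dur, labels = labels,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, spr = spr)
}

read_edf_signal <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1L) {
    stop("mixed per-channel sampling rates are not supported")
  }
  spr <- h$spr[1]
  out <- matrix(0, nrow = h$n_ch, ncol = h$n_rec * spr)
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  for (r in seq_len(h$n_rec)) {
    block <- readBin(con, what = "integer", n = h$n_ch * spr, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) != h$n_ch * spr) stop("truncated EDF data record")
    block <- matrix(block, nrow = spr)
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    out[, cols] <- t((block - rep(h$dig_min, each = spr)) *
                       rep(gain, each = spr) + rep(h$phys_min, each = spr))
  }
  rownames(out) <- h$labels
  out
}

#' EDF quantization step of a recording
#'
#' Half-width of the physical value bin a 16-bit EDF export of this
#' recording resolves; round-trips through EDF are exact to this step.
#'
#' @param recording An [hdsemg_recording()].
#' @return Quantization step in microvolts.
#' @export
edf_quantization_step <- function(recording) {
  phys_max <- max(1e-6, max(abs(recording$signal)))
  2 * phys_max / (32767 - (-32767))
}
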