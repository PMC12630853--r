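# Plain-text interchange formats (hypnograms, event tables, spectra, fit
# records) and a minimal European Data Format (EDF, 16-bit) reader/writer.

#' Read / write a hypnogram as delimited text
#'
#' Two-column tab-separated text with header `epoch_index stage`; stage
#' synonyms (`W`, `R`, numeric AASM codes) are mapped onto
#' Wake/N1/N2/N3/REM on read.
#'
#' @param path File path.
#' @param epoch_s Epoch duration in seconds (default 30).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 30) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(d))) {
    stopf("hypnogram file needs columns epoch_index, stage")
  }
  d <- d[order(d$epoch_index), ]
  if (!identical(as.integer(d$epoch_index), seq_len(nrow(d)))) {
    stopf("epoch_index must be contiguous starting at 1")
  }
  hypnogram(d$stage, epoch_s = epoch_s)
}

#' @rdname read_hypnogram
#' @param hyp A [hypnogram()] to write.
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.table(
    data.frame(epoch_index = seq_along(hyp$stages), stage = hyp$stages),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an event table as delimited text
#'
#' Tab-separated with header `onset_s category`.
#'
#' @param path File path.
#' @param duration_s Optional recording duration; onsets beyond it are
#'   rejected.
#' @return An [event_table()].
#' @export
read_events <- function(path, duration_s = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "category") %in% names(d))) {
    stopf("event file needs columns onset_s, category")
  }
  if (!is.null(duration_s) && any(d$onset_s > duration_s)) {
    stopf("event onset(s) beyond recording end (%g s)", duration_s)
  }
  event_table(d$onset_s, d$category)
}

#' @rdname read_events
#' @param events An [event_table()] to write.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events)[c("onset_s", "category")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a power spectrum as two-column delimited text
#'
#' @param path File path (tab-separated, header `freq_hz power`).
#' @return A [power_spectrum()].
#' @export
read_spectrum <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  power_spectrum(d$freq_hz, d$power, settings = list(source = path))
}

#' @rdname read_spectrum
#' @param spectrum A [power_spectrum()] to write (single channel).
#' @export
write_spectrum <- function(spectrum, path) {
  p <- spectrum$powers
  if (is.matrix(p)) p <- p[, 1L]
  utils::write.table(data.frame(freq_hz = spectrum$freqs, power = p),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- EDF (European Data Format), 16-bit continuous recordings ----------

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a signal to a minimal EDF file
#'
#' Continuous EDF with one data record per second and a physical range
#' covering the data; intended for interchange of synthetic recordings.
#'
#' @param signal An [eeg_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, path) {
  fs <- signal$fs
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  mat <- signal$samples
  ns <- nrow(mat)
  n_rec <- floor(ncol(mat) / fs)
  if (n_rec < 1L) stopf("signal shorter than one 1-s EDF record")
  phys_max <- max(1, ceiling(max(abs(mat))))
  dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic", 80), edf_pad("aperisleep", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44), edf_pad(n_rec, 8),
    edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(signal$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(rep(-phys_max, ns), 8)
  field(rep(phys_max, ns), 8)
  field(rep(-dig_max - 1L, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  scale <- (2 * dig_max + 1) / (2 * phys_max)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- mat[ch, ((r - 1L) * fs + 1L):(r * fs)]
      dig <- as.integer(round(seg * scale))
      writeBin(pmin(pmax(dig, -dig_max - 1L), dig_max), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' Supports continuous 16-bit EDF with identical record durations;
#' samples are rescaled to physical units (assumed uV).
#'
#' @param path EDF file path.
#' @return An [eeg_signal()]; the per-channel sampling rate is taken
#'   from the header.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16)
  fields(80); fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L) stopf("channels with mixed rates unsupported")
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      out[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (dig - dig_min[ch]) * gain + phys_min[ch]
    }
  }
  eeg_signal(out, fs, channel_labels = labels)
}
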