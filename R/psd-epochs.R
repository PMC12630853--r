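# Epoching around events with amplitude-based rejection, segment
# concatenation with zero buffers, and baseline correction.

#' Epoch a signal around event onsets with amplitude rejection
#'
#' Cuts `window_s`-long epochs centered on each onset and masks out trials
#' whose peak-to-peak amplitude exceeds `reject_pp_uv` (default 1000 uV).
#' Onsets too close to the recording edge are dropped.
#'
#' @param signal An [eeg_signal()] or numeric vector.
#' @param onsets Event onsets in seconds.
#' @param fs Sampling rate (ignored for `eeg_signal` input).
#' @param window_s Epoch length in seconds (default 10), centered on the
#'   onset.
#' @param reject_pp_uv Peak-to-peak rejection threshold in uV.
#' @param channel Channel for multi-channel input.
#' @return A list of class `epoch_set`: `epochs` (trials x time matrix),
#'   `t_zero` (onset sample index within the epoch), `fs`, `kept_mask`
#'   (FALSE for amplitude-rejected trials), `onsets` (the retained onset
#'   times), and `n_dropped_edge`.
#' @export
epoch_and_reject <- function(signal, onsets, fs = NULL, window_s = 10,
                             reject_pp_uv = 1000, channel = 1L) {
  if (inherits(signal, "eeg_signal")) {
    fs <- signal$fs
    x <- signal_channel(signal, channel)
  } else {
    if (is.null(fs)) stopf("`fs` required for plain numeric input")
    x <- as.numeric(signal)
  }
  half <- round(window_s / 2 * fs)
  n <- length(x)
  start <- round(onsets * fs) + 1L - half
  ok <- start >= 1L & (start + 2L * half - 1L) <= n
  n_edge <- sum(!ok)
  if (n_edge > 0) {
    message(sprintf("epoch_and_reject: dropped %d onset(s) at recording edge",
                    n_edge))
  }
  start <- start[ok]
  if (!length(start)) stopf("no epochs fit inside the recording")
  epochs <- t(vapply(start, function(s) x[s:(s + 2L * half - 1L)],
                     numeric(2L * half)))
  pp <- apply(epochs, 1L, function(e) diff(range(e)))
  kept <- pp <= reject_pp_uv
  structure(list(epochs = epochs, t_zero = half + 1L, fs = fs,
                 kept_mask = kept, onsets = onsets[ok],
                 n_dropped_edge = n_edge),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d kept) x %d samples @ %g Hz\n",
              nrow(x$epochs), sum(x$kept_mask), ncol(x$epochs), x$fs))
  invisible(x)
}

#' Concatenate artefact-free segments with zero buffers
#'
#' Demeans each segment, joins segments with 2-s zero-amplitude buffers,
#' and zero-pads the result to a fixed total duration (default 68 s, i.e.
#' up to 60 s of data plus up to four 2-s buffers).
#'
#' @param segments List of numeric vectors (1 to `max_segments`).
#' @param fs Sampling rate in Hz.
#' @param buffer_s Buffer duration in seconds (default 2).
#' @param target_s Total output duration in seconds (default 68).
#' @param max_segments Maximum number of segments (default 5).
#' @return An [eeg_signal()]; the sample ranges of buffers and padding are
#'   recorded in `attr(, "provenance")`.
#' @export
concatenate_with_buffers <- function(segments, fs, buffer_s = 2,
                                     target_s = 68, max_segments = 5) {
  if (!is.list(segments) || !length(segments)) {
    stopf("`segments` must be a non-empty list")
  }
  if (length(segments) > max_segments) {
    stopf("more than %d segments supplied", max_segments)
  }
  buf <- rep(0, round(buffer_s * fs))
  pieces <- list()
  zero_ranges <- list()
  pos <- 0L
  for (i in seq_along(segments)) {
    seg <- as.numeric(segments[[i]])
    seg <- seg - mean(seg)
    pieces[[length(pieces) + 1L]] <- seg
    pos <- pos + length(seg)
    if (i < length(segments)) {
      pieces[[length(pieces) + 1L]] <- buf
      zero_ranges[[length(zero_ranges) + 1L]] <-
        c(pos + 1L, pos + length(buf))
      pos <- pos + length(buf)
    }
  }
  x <- unlist(pieces)
  n_target <- round(target_s * fs)
  if (length(x) > n_target) {
    stopf("segments plus buffers exceed target duration (%g s)", target_s)
  }
  if (length(x) < n_target) {
    zero_ranges[[length(zero_ranges) + 1L]] <- c(length(x) + 1L, n_target)
    x <- c(x, rep(0, n_target - length(x)))
  }
  out <- eeg_signal(x, fs)
  attr(out, "provenance") <- list(buffer_s = buffer_s, target_s = target_s,
                                  zero_sample_ranges = zero_ranges)
  out
}

#' Baseline-correct a timecourse
#'
#' `subtract` mode (for aperiodic-parameter traces) removes the baseline
#' mean; `relative` mode (for ERPs) computes
#' `(data - baseline mean) / baseline mean`.
#'
#' @param values Numeric vector, or trials-by-time matrix (per-trial
#'   baselines).
#' @param times Time stamps in seconds matching the columns of `values`
#'   (0 = event onset).
#' @param baseline_window `c(t0, t1)` in seconds (default `c(-0.5, 0)`).
#' @param mode `"subtract"` or `"relative"`.
#' @return Corrected values, same shape; baseline mean(s) in
#'   `attr(, "baseline_mean")`.
#' @export
baseline_correct <- function(values, times,
                             baseline_window = c(-0.5, 0),
                             mode = c("subtract", "relative")) {
  mode <- match.arg(mode)
  vec <- !is.matrix(values)
  if (vec) values <- matrix(values, nrow = 1L)
  if (length(times) != ncol(values)) {
    stopf("`times` must match the columns of `values`")
  }
  in_base <- times >= baseline_window[1] & times < baseline_window[2]
  if (!any(in_base)) stopf("baseline window not within timecourse")
  bmean <- rowMeans(values[, in_base, drop = FALSE], na.rm = TRUE)
  if (mode == "relative" && any(abs(bmean) < .Machine$double.eps)) {
    stopf("zero baseline mean in relative mode")
  }
  out <- if (mode == "subtract") values - bmean else (values - bmean) / bmean
  if (vec) out <- out[1L, ]
  attr(out, "baseline_mean") <- bmean
  out
}
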