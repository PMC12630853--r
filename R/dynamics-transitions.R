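# Stage-transition extraction and transition-locked aperiodic traces.

#' Extract sleep-stage transitions with matched baselines
#'
#' Finds transitions of the requested kinds whose +/-60 s window lies
#' fully inside the recording, and samples (seeded) an equal number of
#' 120-s continuous same-stage baseline spans of the pre-transition stage
#' that do not overlap any transition window.
#'
#' @param hyp A [hypnogram()] (>= 5 epochs).
#' @param kinds Character vector of transitions as `"from->to"`; the
#'   special form `"NREM->REM"` matches N2 or N3 into REM. Default:
#'   `c("N1->N2", "N2->N1", "N2->N3", "NREM->REM")`.
#' @param window_s Half-window around the transition (default 60).
#' @param seed Seed for baseline sampling.
#' @return A list of class `transition_set`: `transitions` (tibble:
#'   time_s, from, to, kind) and `baselines` (tibble: time_s, stage,
#'   kind); transitions without a qualifying baseline are flagged in
#'   `baseline_missing`.
#' @export
extract_transitions <- function(hyp,
                                kinds = c("N1->N2", "N2->N1", "N2->N3",
                                          "NREM->REM"),
                                window_s = 60, seed = 1) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(hyp$stages) < 5L) stopf("hypnogram must have >= 5 epochs")
  st <- hyp$stages
  es <- hyp$epoch_s
  dur <- length(st) * es
  match_kind <- function(from, to) {
    for (kd in kinds) {
      parts <- strsplit(kd, "->", fixed = TRUE)[[1]]
      from_ok <- if (parts[1] == "NREM") from %in% c("N2", "N3") else
        from == parts[1]
      to_ok <- if (parts[2] == "NREM") to %in% c("N2", "N3") else
        to == parts[2]
      if (from_ok && to_ok) return(kd)
    }
    NA_character_
  }
  rows <- list()
  for (i in seq_len(length(st) - 1L)) {
    if (st[i] == st[i + 1L]) next
    kd <- match_kind(st[i], st[i + 1L])
    if (is.na(kd)) next
    t_tr <- hyp$start_time_s + i * es  # boundary between epoch i and i+1
    if (t_tr - window_s < hyp$start_time_s || t_tr + window_s > dur) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time_s = t_tr, from = st[i], to = st[i + 1L], kind = kd)
  }
  transitions <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(time_s = numeric(0), from = character(0),
                   to = character(0), kind = character(0))
  # candidate baseline spans: runs of >= 2*window_s/epoch_s same-stage
  # epochs, centers not overlapping any transition window
  n_span <- ceiling(2 * window_s / es)
  runs <- rle(st)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- list()
  for (r in seq_along(runs$values)) {
    if (runs$lengths[r] < n_span) next
    for (s0 in starts[r]:(ends[r] - n_span + 1L)) {
      center <- hyp$start_time_s + (s0 - 1L) * es + window_s
      overlap <- length(transitions$time_s) &&
        any(abs(transitions$time_s - center) < 2 * window_s)
      if (!overlap) {
        cand[[length(cand) + 1L]] <- tibble::tibble(
          time_s = center, stage = runs$values[r])
      }
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    tibble::tibble(time_s = numeric(0), stage = character(0))
  baselines <- list()
  baseline_missing <- logical(nrow(transitions))
  if (nrow(transitions)) {
    bl_seed <- seed_stream(seed, nrow(transitions))
    for (i in seq_len(nrow(transitions))) {
      pre <- transitions$from[i]
      avail <- cand[cand$stage == pre, , drop = FALSE]
      if (!nrow(avail)) {
        baseline_missing[i] <- TRUE
        next
      }
      pick <- with_seed(bl_seed[[i]], avail[sample.int(nrow(avail), 1L), ])
      pick$kind <- transitions$kind[i]
      baselines[[length(baselines) + 1L]] <- pick
    }
  }
  baselines <- if (length(baselines)) do.call(rbind, baselines) else
    tibble::tibble(time_s = numeric(0), stage = character(0),
                   kind = character(0))
  structure(list(transitions = transitions, baselines = baselines,
                 baseline_missing = baseline_missing,
                 window_s = window_s),
            class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  cat(sprintf("<transition_set> %d transition(s), %d baseline span(s)\n",
              nrow(x$transitions), nrow(x$baselines)))
  if (nrow(x$transitions)) print(table(x$transitions$kind))
  invisible(x)
}

#' Transition-locked feature traces
#'
#' Aligns a time-resolved feature trace (e.g. the exponent from
#' [sliding_psd()] + [time_resolved_fit()]) to each transition and to
#' each matched baseline center, on a regular grid spanning
#' `[-window_s, +window_s]` at the timecourse's step (61 samples at a 2-s
#' step over +/-60 s). Trials with more than `max_gap_frac` missing
#' samples are dropped.
#'
#' @param timecourse A [feature_timecourse()] with absolute times.
#' @param transitions A `transition_set` from [extract_transitions()].
#' @param feature Trace column to align (default `"exponent"`).
#' @param step_s Grid step in seconds (default 2).
#' @param kind Restrict to one transition kind, or `NULL` for all.
#' @param max_gap_frac Maximum fraction of missing samples per trial
#'   (default 0.2).
#' @return A list with `rel_times`, `transition` and `baseline`
#'   (trials-by-time matrices), and per-column means/SEM in `summary`.
#' @export
transition_locked_traces <- function(timecourse, transitions,
                                     feature = "exponent", step_s = 2,
                                     kind = NULL, max_gap_frac = 0.2) {
  w <- transitions$window_s
  rel <- seq(-w, w, by = step_s)
  tr <- transitions$transitions
  bl <- transitions$baselines
  if (!is.null(kind)) {
    tr <- tr[tr$kind == kind, , drop = FALSE]
    bl <- bl[bl$kind == kind, , drop = FALSE]
  }
  align <- function(centers) {
    if (!length(centers)) {
      return(matrix(numeric(0), nrow = 0, ncol = length(rel)))
    }
    out <- t(vapply(centers, function(t0) {
      target <- t0 + rel
      idx <- vapply(target, function(tt) {
        d <- abs(timecourse$times - tt)
        i <- which.min(d)
        if (d[i] <= step_s / 2 + 1e-9) i else NA_integer_
      }, integer(1))
      v <- rep(NA_real_, length(rel))
      v[!is.na(idx)] <- timecourse$values[[feature]][idx[!is.na(idx)]]
      v
    }, numeric(length(rel))))
    keep <- rowMeans(is.na(out)) <= max_gap_frac
    if (any(!keep)) {
      message(sprintf("transition_locked_traces: dropped %d gappy trial(s)",
                      sum(!keep)))
    }
    out[keep, , drop = FALSE]
  }
  mt <- align(tr$time_s)
  mb <- align(bl$time_s)
  summ <- tibble::tibble(
    rel_time_s = rel,
    transition_mean = if (nrow(mt)) colMeans(mt, na.rm = TRUE) else NA_real_,
    transition_sem = if (nrow(mt) > 1)
      apply(mt, 2, stats::sd, na.rm = TRUE) / sqrt(nrow(mt)) else NA_real_,
    baseline_mean = if (nrow(mb)) colMeans(mb, na.rm = TRUE) else NA_real_,
    baseline_sem = if (nrow(mb) > 1)
      apply(mb, 2, stats::sd, na.rm = TRUE) / sqrt(nrow(mb)) else NA_real_)
  list(rel_times = rel, transition = mt, baseline = mb, summary = summ)
}
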