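#' Detect the response saccade on bipolar horizontal EOG
#'
#' Horizontal eye movements create a moving dipole whose sign on the
#' difference of the two canthus electrodes (right minus left) encodes
#' direction: positive deflections are rightward, negative leftward. The
#' difference trace is low-pass filtered at 20 Hz (zero-phase Butterworth,
#' order 4), a 3-second window starting at the question onset is scanned, and
#' the first local extremum whose distance from the window mean exceeds
#' `threshold_sd` standard deviations and whose latency is at least
#' `min_latency_ms` is taken as the response saccade. If no such peak exists
#' the trial is invalid.
#'
#' @param eog_left,eog_right Voltage series of the left- and right-canthus
#'   electrodes (full recording or any segment containing the window).
#' @param question_onset_s Question onset in seconds relative to the start of
#'   the supplied series.
#' @param sfreq Sampling rate, Hz.
#' @param window_s Length of the scanned post-question window, seconds.
#' @param threshold_sd Peak threshold in window-SD units.
#' @param min_latency_ms Minimum accepted saccade latency, milliseconds.
#' @param stats_scope `"window"` computes the mean/SD threshold from the
#'   scanned 3 s window of the trial itself; `"series"` uses the whole
#'   supplied difference trace (per-session statistics).
#' @return A list with `valid` (flag), `direction` (`"left"`, `"right"` or
#'   `"none"`), and `rt_ms` (latency from question onset, `NA` when invalid).
#' @export
detect_saccade <- function(eog_left, eog_right, question_onset_s, sfreq,
                           window_s = 3, threshold_sd = 1.5,
                           min_latency_ms = 150,
                           stats_scope = c("window", "series")) {
  stats_scope <- match.arg(stats_scope)
  n <- length(eog_right)
  stopifnot(length(eog_left) == n)
  start <- round(question_onset_s * sfreq) + 1L
  stop_ <- start + round(window_s * sfreq) - 1L
  if (start < 1L || stop_ > n) {
    return(list(valid = FALSE, direction = "none", rt_ms = NA_real_))
  }
  d <- eog_right - eog_left
  bf <- signal::butter(4, 20 / (sfreq / 2), type = "low")
  d <- signal::filtfilt(bf, d)
  w <- d[start:stop_]
  ref <- if (stats_scope == "window") w else d
  m <- mean(ref); s <- sd(ref)
  if (!is.finite(s) || s == 0) {
    return(list(valid = FALSE, direction = "none", rt_ms = NA_real_))
  }
  z <- w - m
  ## local extrema of the centred trace (either polarity)
  dz <- diff(z)
  ext <- which(dz[-length(dz)] * dz[-1] <= 0 & dz[-length(dz)] != 0) + 1L
  lat_ms <- (ext - 1L) / sfreq * 1000
  hit <- ext[abs(z[ext]) > threshold_sd * s & lat_ms >= min_latency_ms]
  if (length(hit) == 0L) {
    return(list(valid = FALSE, direction = "none", rt_ms = NA_real_))
  }
  peak <- hit[1]
  list(valid = TRUE,
       direction = if (z[peak] > 0) "right" else "left",
       rt_ms = (peak - 1L) / sfreq * 1000)
}

#' Score all trials of a recording behaviorally
#'
#' Runs [detect_saccade()] on every question of a recording's trial table and
#' decodes correctness: a question of positive polarity demands a "yes", and
#' `side_mapping` translates the answer into the demanded saccade side.
#'
#' @param rec An [eeg_recording()] containing the two EOG channels.
#' @param trials Trial table for the recording.
#' @param side_mapping Named vector mapping `"yes"`/`"no"` to
#'   `"left"`/`"right"` for this subject.
#' @param eog_channels Labels of the left and right EOG channels in `rec`.
#' @param ... Passed to [detect_saccade()].
#' @return The behavior table: `data.frame` with columns `trial_id`, `valid`,
#'   `direction`, `rt_ms`, `correct`.
#' @export
score_trials <- function(rec, trials,
                         side_mapping = c(yes = "right", no = "left"),
                         eog_channels = c("EOG_L", "EOG_R"), ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!setequal(names(side_mapping), c("yes", "no")) ||
      !all(side_mapping %in% c("left", "right"))) {
    stop("`side_mapping` must map yes/no to left/right", call. = FALSE)
  }
  idx <- channel_index(rec, eog_channels)
  el <- rec$data[idx[1], ]
  er <- rec$data[idx[2], ]
  sf <- rec$sfreq
  n <- length(el)
  pre_s <- 0.5                       # filter settle-in context before the question
  res <- lapply(seq_len(nrow(trials)), function(k) {
    q0 <- trials$question_onset_s[k]
    i0 <- max(1L, round((q0 - pre_s) * sf) + 1L)
    i1 <- min(n, round((q0 + 3.5) * sf))
    detect_saccade(el[i0:i1], er[i0:i1],
                   question_onset_s = q0 - (i0 - 1L) / sf, sf, ...)
  })
  direction <- vapply(res, `[[`, character(1), "direction")
  valid <- vapply(res, `[[`, logical(1), "valid")
  rt_ms <- vapply(res, `[[`, numeric(1), "rt_ms")
  demanded <- unname(side_mapping[
    ifelse(trials$question_polarity == "positive", "yes", "no")])
  data.frame(trial_id = trials$trial_id,
             valid = valid,
             direction = direction,
             rt_ms = rt_ms,
             correct = valid & direction == demanded,
             stringsAsFactors = FALSE)
}
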