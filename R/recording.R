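#' Continuous multichannel recording container
#'
#' Lightweight container for a continuous EEG/EOG recording: a channels x
#' samples voltage matrix (microvolts), a sampling rate, channel labels and
#' types, and an event table with onsets in seconds.
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param sfreq Sampling rate in Hz.
#' @param ch_names Character vector of channel labels (10-20 names plus EOG).
#' @param ch_types Character vector, `"eeg"` or `"eog"` per channel.
#' @param events `data.frame` with columns `onset_s`, `label` and
#'   (optionally) `trial_id`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, ch_names, ch_types, events) {
  stopifnot(is.matrix(data), nrow(data) == length(ch_names),
            length(ch_names) == length(ch_types), sfreq > 0)
  if (missing(events) || is.null(events)) {
    events <- data.frame(onset_s = numeric(0), label = character(0),
                         trial_id = integer(0))
  }
  stopifnot(all(c("onset_s", "label") %in% names(events)))
  rownames(data) <- ch_names
  structure(list(data = data, sfreq = sfreq, ch_names = ch_names,
                 ch_types = ch_types, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  cat(sprintf("  channels: %s\n", paste(x$ch_names, collapse = " ")))
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(names(table(x$events$label)), collapse = ", ")))
  invisible(x)
}

#' Epoched data container
#'
#' Trials x channels x samples array time-locked to an event, with the epoch
#' time axis in milliseconds and a link to per-trial metadata.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param times_ms Numeric vector of sample times relative to the locking
#'   event, milliseconds.
#' @param ch_names,ch_types Channel labels and types.
#' @param sfreq Sampling rate in Hz.
#' @param metadata `data.frame` with one row per retained trial.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times_ms, ch_names, ch_types, sfreq, metadata) {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == length(ch_names),
            dim(data)[3] == length(times_ms),
            dim(data)[1] == nrow(metadata))
  structure(list(data = data, times_ms = times_ms, ch_names = ch_names,
                 ch_types = ch_types, sfreq = sfreq, metadata = metadata),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  window: [%g, %g] ms\n", min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

## index of a channel label, with a helpful error
channel_index <- function(obj, ch) {
  idx <- match(ch, obj$ch_names)
  if (anyNA(idx)) {
    stop(sprintf("channel(s) not found: %s",
                 paste(ch[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  idx
}
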